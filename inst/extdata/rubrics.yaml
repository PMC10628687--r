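# Default pediatric Life's Essential 8 scoring rubric.
# Every band list is ordered by `lower` and read as left-closed intervals
# [lower_i, lower_{i+1}) on the named metric; the last band is unbounded.
# Points are 0-100. All values are configuration: override with a copy of
# this file.

diet:
  # adherence total mapped through population quintile bands (Q20..Q80)
  points: [0, 25, 50, 80, 100]

physical_activity:
  # metric: weekly physical-activity minutes
  bands:
    - {lower: 0, points: 0}
    - {lower: 1, points: 20}
    - {lower: 120, points: 40}
    - {lower: 240, points: 60}
    - {lower: 300, points: 80}
    - {lower: 360, points: 90}
    - {lower: 420, points: 100}

nicotine:
  categories:
    never: 100
    former_gt30d: 50
    current_le30d: 0
  secondhand_penalty: 20

sleep:
  # Healthy China Initiative recommendations by schooling band
  recommended_hours:
    - {age_min: 7, age_max: 13, hours: 10}
    - {age_min: 13, age_max: 16, hours: 9}
    - {age_min: 16, age_max: 20, hours: 8}
  # metric: sleep_hours - recommended_hours (negative = deficit)
  bands:
    - {lower: -.inf, points: 0}
    - {lower: -4, points: 20}
    - {lower: -3, points: 40}
    - {lower: -2, points: 70}
    - {lower: -1, points: 90}
    - {lower: 0, points: 100}

bmi:
  # metric: BMI-for-age percentile; above the 95th percentile the metric
  # switches to the ratio BMI / (95th-percentile BMI)
  percentile_bands:
    - {lower: 0, points: 100}
    - {lower: 85, points: 70}
  ratio_bands:
    - {lower: 1.0, points: 30}
    - {lower: 1.2, points: 15}
    - {lower: 1.4, points: 0}

lipids:
  # metric: non-HDL cholesterol, mg/dL
  bands:
    - {lower: 0, points: 100}
    - {lower: 130, points: 60}
    - {lower: 160, points: 40}
    - {lower: 190, points: 20}
    - {lower: 220, points: 0}

glucose:
  diabetes_fpg: 126
  # HbA1c fallback thresholds (%) when FPG is missing and there is no
  # diagnosis: below first -> optimal, below second -> intermediate,
  # at/above second -> scored on the diabetic HbA1c bands
  nondiabetic_hba1c: [5.7, 6.5]
  # metric without diabetes: fasting plasma glucose, mg/dL
  fpg_bands:
    - {lower: 0, points: 100}
    - {lower: 100, points: 60}
  # metric with diabetes (diagnosis, or FPG >= diabetes_fpg): HbA1c, %
  hba1c_bands:
    - {lower: 0, points: 40}
    - {lower: 7, points: 30}
    - {lower: 8, points: 20}
    - {lower: 9, points: 10}
    - {lower: 10, points: 0}

blood_pressure:
  # children below adult_age: percentile bands normal/elevated/stage1, with
  # stage 2 at the 95th-percentile pressure + stage2_offset_mmhg;
  # from adult_age on: adult mmHg cutoffs (elevated requires DBP < 80)
  adult_age: 13
  youth_percentiles: [90, 95]
  stage2_offset_mmhg: 12
  adult_sbp: [120, 130, 140]
  adult_dbp: [80, 90]
  points: [100, 75, 50, 0]
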