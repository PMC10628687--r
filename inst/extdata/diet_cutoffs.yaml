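# Default population quintile cutoffs for DASH-style diet adherence scoring.
# Per food group: quintile cutoffs (Q20, Q40, Q60, Q80) of daily intake in
# g/day, with direction "higher" (more is better) or "lower" (less is
# better), plus a plausible sampling range used by the synthetic generator.
# The adherence total (8 groups x 1-5 quintile points, range 8-40) is mapped
# through `adherence_cutoffs` to the diet rubric points.
# These are synthetic defaults standing in for cutoffs estimated on an
# analysis population; estimate_diet_cutoffs() recomputes them from data.

groups:
  vegetables:   {direction: higher, cutoffs: [100, 175, 250, 350], range: [0, 600]}
  fruits:       {direction: higher, cutoffs: [20, 60, 120, 200], range: [0, 400]}
  whole_grains: {direction: higher, cutoffs: [10, 30, 60, 120], range: [0, 250]}
  milk:         {direction: higher, cutoffs: [5, 25, 80, 150], range: [0, 350]}
  beans:        {direction: higher, cutoffs: [5, 15, 30, 60], range: [0, 150]}
  fish:         {direction: higher, cutoffs: [5, 15, 30, 60], range: [0, 150]}
  salt:         {direction: lower, cutoffs: [4, 6, 8, 10], range: [1, 16]}
  ssb:          {direction: lower, cutoffs: [10, 50, 120, 250], range: [0, 500]}

adherence_cutoffs: [20, 23, 25, 28]
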