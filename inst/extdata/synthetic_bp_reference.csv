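sex,measure,term,coefficient
male,SBP,intercept,102
male,SBP,age1,1.6
male,SBP,age2,0.03
male,SBP,height1,1.8
male,SBP,height2,0.12
male,SBP,residual_sd,10.5
female,SBP,intercept,101
female,SBP,age1,1.4
female,SBP,age2,0.02
female,SBP,height1,1.6
female,SBP,height2,0.1
female,SBP,residual_sd,10.2
male,DBP,intercept,61
male,DBP,age1,0.7
male,DBP,age2,0.01
male,DBP,height1,1
male,DBP,residual_sd,9.2
female,DBP,intercept,60.5
female,DBP,age1,0.65
female,DBP,age2,0.01
female,DBP,height1,0.95
female,DBP,residual_sd,9
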