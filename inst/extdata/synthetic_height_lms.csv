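sex,age_months,L,M,S
male,84,1,121,0.042
male,96,1,126.88,0.042
male,108,1,131.97,0.042
male,120,1,136.79,0.042
male,132,1,141.46,0.042
male,144,1,146.01,0.042
male,156,1,150.47,0.042
male,168,1,154.86,0.042
male,180,1,159.18,0.042
male,192,1,163.45,0.042
male,204,1,167.68,0.042
male,216,1,171.86,0.042
male,228,1,176,0.042
female,84,1,120,0.04
female,96,1,126.67,0.04
female,108,1,131.22,0.04
female,120,1,135.2,0.04
female,132,1,138.86,0.04
female,144,1,142.3,0.04
female,156,1,145.57,0.04
female,168,1,148.7,0.04
female,180,1,151.72,0.04
female,192,1,154.65,0.04
female,204,1,157.5,0.04
female,216,1,160.28,0.04
female,228,1,163,0.04
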