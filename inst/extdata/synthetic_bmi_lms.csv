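sex,age_months,L,M,S
male,84,-2.2,15.2,0.11
male,96,-2.1333,15.477,0.1125
male,108,-2.0667,15.882,0.115
male,120,-2,16.355,0.1175
male,132,-1.9333,16.878,0.12
male,144,-1.8667,17.443,0.1225
male,156,-1.8,18.043,0.125
male,168,-1.7333,18.674,0.1275
male,180,-1.6667,19.332,0.13
male,192,-1.6,20.016,0.1325
male,204,-1.5333,20.723,0.135
male,216,-1.4667,21.451,0.1375
male,228,-1.4,22.2,0.14
female,84,-2,15.3,0.105
female,96,-1.9333,15.63,0.1071
female,108,-1.8667,16.057,0.1092
female,120,-1.8,16.532,0.1113
female,132,-1.7333,17.039,0.1133
female,144,-1.6667,17.573,0.1154
female,156,-1.6,18.129,0.1175
female,168,-1.5333,18.704,0.1196
female,180,-1.4667,19.296,0.1217
female,192,-1.4,19.902,0.1238
female,204,-1.3333,20.523,0.1258
female,216,-1.2667,21.156,0.1279
female,228,-1.2,21.8,0.13
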