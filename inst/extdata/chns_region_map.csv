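province,region
Beijing,North China
Heilongjiang,Northeast China
Liaoning,Northeast China
Jiangsu,East China
Shandong,East China
Shanghai,East China
Zhejiang,East China
Henan,Central China
Hubei,Central China
Hunan,Central China
Guangxi,Central China
Guizhou,Southwest China
Chongqing,Southwest China
Yunnan,Southwest China
Shaanxi,Northwest China
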