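sample_id,area,bean_type,element,value,censored,lod
T001,Hangzhou,soybean,Cd,0.05,0,0.00024
T002,Hangzhou,soybean,Cd,0.489,0,0.00024
T003,Ningbo,soybean,Cd,0.02,0,0.00024
T004,Ningbo,soybean,Cd,0.12,0,0.00024
T001,Hangzhou,soybean,Pb,0.031,0,0.00024
T002,Hangzhou,soybean,Pb,,1,0.00024
T003,Ningbo,soybean,Pb,0.012,0,0.00024
T004,Ningbo,soybean,Pb,,1,0.00024
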