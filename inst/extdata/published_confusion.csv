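table,stratum,population,tp,fn,fp,tn
t2,male,all_population,765,1337,229815,1064605
t3,male,excluding_development,339,1243,229815,1064605
t5,female,all_population,397,356,158025,1158198
t6,female,excluding_development,223,280,158025,1158198
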