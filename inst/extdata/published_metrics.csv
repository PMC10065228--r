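table,stratum,row,sensitivity,specificity,ppv,npv,accuracy,f_value
t1,male,training,59.74,81.76,76.65,67.00,70.75,67.14
t1,male,testing,60.74,81.45,76.69,67.46,71.09,67.77
t1,male,validation,21.43,82.25,0.15,99.88,82.17,0.30
t4,female,training,48.57,88.43,80.77,63.23,68.50,60.66
t4,female,testing,45.33,87.44,78.30,61.53,66.39,57.42
t4,female,validation,52.72,87.99,0.25,99.97,87.97,0.50
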