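age_min_days,age_max_days,sex,upper_limit_umol_l
29,365,any,35
365,1825,any,42
1825,3650,any,52
3650,4745,any,62
4745,6570,any,80
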