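cohort,subset,new,waxing_crescent,first_quarter,waxing_gibbous,full,waning_gibbous,last_quarter,waning_crescent
European,total,3362,3533,3423,3354,3393,3319,3276,3252
North American,total,356,367,382,422,431,382,407,390
European,mean_28_30,1321,1440,1379,1284,1273,1259,1198,1189
North American,mean_28_30,105,114,127,165,197,136,154,152
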