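sao2_range,group,n,mean_rcso2,se_rcso2,n_flagged,pct_flagged
95-100,control,17,48.5,1.6,1,5
95-100,oa,11,44.1,1.0,7,64
90-95,control,3,47.3,3.5,0,0
90-95,oa,5,40.8,0.8,4,80
85-90,control,1,37,0,1,100
85-90,oa,3,35.5,1.2,3,100
<85,control,3,36.6,2.7,2,67
<85,oa,9,30.1,2.6,8,89
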