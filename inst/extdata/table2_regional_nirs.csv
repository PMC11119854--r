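site,group,period,mean,se
brain,control,baseline,50.4,2.7
brain,control,post1h,48.3,2.6
brain,control,fio2_40,47.5,2.5
brain,control,fio2_30,46.3,2.6
brain,control,fio2_21,41.2,3.2
brain,oa,baseline,54.6,2.6
brain,oa,post1h,44.9,1.4
brain,oa,fio2_40,42.6,0.7
brain,oa,fio2_30,38.4,1.0
brain,oa,fio2_21,27.9,2.6
gut,control,baseline,66.5,6.2
gut,control,post1h,57.8,7.4
gut,control,fio2_40,57.7,5.8
gut,control,fio2_30,53.5,4.1
gut,control,fio2_21,46.5,4.7
gut,oa,baseline,61.9,4.4
gut,oa,post1h,53.3,2.7
gut,oa,fio2_40,50.6,2.0
gut,oa,fio2_30,44.7,2.3
gut,oa,fio2_21,32.0,2.5
kidney,control,baseline,47.7,6.0
kidney,control,post1h,48.6,2.7
kidney,control,fio2_40,49.6,2.4
kidney,control,fio2_30,48.6,2.5
kidney,control,fio2_21,45.4,2.8
kidney,oa,baseline,60.6,5.0
kidney,oa,post1h,52.6,5.7
kidney,oa,fio2_40,50.4,4.2
kidney,oa,fio2_30,47.0,4.0
kidney,oa,fio2_21,34.0,3.2
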