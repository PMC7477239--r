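primate_id,group,sex,age_years,baseline_iop_od,baseline_iop_od_sd,baseline_iop_os,baseline_iop_os_sd,n_injections,onset_weeks,mean_iop_m2_7_od,mean_iop_m2_7_od_sd,mean_iop_m2_7_os,mean_iop_m2_7_os_sd,max_iop_m2_7_od,max_iop_m2_7_od_sd,max_iop_m2_7_os,max_iop_m2_7_os_sd
3914,1,F,9,16.0,0.5,14.0,1.0,5,4,46.0,16.9,24.0,1.9,59.0,20.1,27.0,3.1
5186,1,F,9,10.0,0.9,10.0,1.2,7,6,40.0,14.3,15.0,1.5,51.0,21.3,18.0,1.9
5187,1,F,9,9.0,0.4,9.0,0.4,7,6,32.0,18.3,15.0,1.4,44.0,24.7,17.0,1.9
5189,1,F,9,10.0,0.6,10.0,0.9,8,7,47.0,16.6,16.0,1.4,55.0,18.8,18.0,1.2
5191,1,F,9,9.0,0.5,12.0,0.5,6,5,53.0,16.0,17.0,1.1,61.0,19.8,20.0,1.6
5192,1,F,5,12.0,1.0,11.0,1.0,6,5,38.0,18.7,21.0,1.2,49.0,16.7,23.0,1.0
5194,1,F,9,13.0,0.5,11.0,0.5,7,6,41.0,13.6,17.0,1.3,49.0,20.2,19.0,2.3
5195,1,F,9,12.0,0.6,12.0,1.2,6,5,43.0,18.2,17.0,1.2,54.0,17.3,20.0,2.3
5234,1,F,9,15.0,0.6,14.0,0.6,5,4,38.0,14.1,17.0,1.0,53.0,17.3,19.0,0.6
5235,1,F,9,14.0,0.6,16.0,0.6,6,5,50.0,15.2,19.0,1.4,61.0,16.2,20.0,0.8
2677,2,F,5,13.0,1.2,15.0,1.7,6,5,26.0,11.5,24.0,9.2,33.0,8.30,38.0,10.8
2705,2,F,5,16.0,1.7,15.0,2.3,6,5,29.0,10.7,23.0,6.7,27.0,7.2,39.0,10.5
5407,2,F,5,14.0,1.9,12.0,1.7,3,2,35.0,21.0,37.0,16.3,46.0,21.5,50.0,16.4
5408,2,F,5,15.0,0.5,14.0,0.6,6,5,32.0,10.5,32.0,10.9,38.0,9.3,37.0,12.2
2873,2,M,4,16.0,2.9,17.0,2.1,6,5,31.0,15.6,38.0,17.1,53.0,16.9,41.0,15.1
2874,2,M,4,12.0,2.3,16.0,1.0,5,4,33.0,13.9,32.0,10.3,39.0,11.5,41.0,15.4
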