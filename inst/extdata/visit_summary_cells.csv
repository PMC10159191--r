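species,receiver_id,unique_tags,range_min_lo,range_min_hi,mean_min,se_min,n_visits,total_time_min
R_brasiliensis,IR16,2,0.6,1554.7,63.1,4.8,1200,75665.0
R_brasiliensis,SCLN,1,1.6,24.1,10.6,2.1,13,138.1
R_brasiliensis,SCLS,1,1.9,34.4,14.7,2.2,20,293.8
R_brasiliensis,SINJ,1,2.5,66.3,14.2,6.7,9,127.7
R_brasiliensis,SISO,1,1.1,29.5,7.6,1.5,25,190.6
R_brasiliensis,SIWP,2,2.1,4.8,3.8,0.9,3,11.4
R_bonasus,IR16,10,0.7,194.9,31.5,2.6,230,7239.9
R_bonasus,SCLN,10,0.8,387.5,33.0,2.5,289,9536.3
R_bonasus,SCLS,9,0.9,138.0,24.2,1.9,188,4541.9
R_bonasus,SINJ,10,0.8,213.0,25.4,2.7,186,4715.4
R_bonasus,SISO,13,0.6,298.3,15.3,1.0,403,6169.9
R_bonasus,SIWP,11,0.6,200.1,12.8,2.1,131,1672.4
A_narinari,IR16,16,0.7,604.5,34.1,1.3,1036,35339.9
A_narinari,SCLN,16,0.6,220.1,19.8,0.7,886,17541.9
A_narinari,SCLS,15,0.8,207.1,30.0,2.0,264,7917.7
A_narinari,SINJ,20,0.6,927.4,39.4,0.7,7061,278371.9
A_narinari,SISO,18,0.6,514.4,17.0,0.4,3805,64827.4
A_narinari,SIWP,18,0.6,82.3,7.6,0.2,1265,9584.5
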