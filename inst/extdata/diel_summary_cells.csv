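species,receiver_id,diel,mean,se,total
R_brasiliensis,IR16,day,64.0,0.9,13762
R_brasiliensis,IR16,night,95.8,1.1,21848
R_brasiliensis,SCLN,day,4.1,0.7,29
R_brasiliensis,SCLN,night,4.4,0.5,22
R_brasiliensis,SCLS,day,10.8,1.2,54
R_brasiliensis,SCLS,night,5.1,0.8,61
R_brasiliensis,SINJ,day,6.7,1.3,47
R_brasiliensis,SINJ,night,4.0,0.0,4
R_brasiliensis,SISO,day,3.3,0.3,92
R_brasiliensis,SISO,night,2.5,0.3,35
R_brasiliensis,SIWP,day,2.0,0.4,6
R_brasiliensis,SIWP,night,1.7,0.5,5
R_bonasus,IR16,day,12.4,0.6,1031
R_bonasus,IR16,night,17.1,0.6,1748
R_bonasus,SCLN,day,12.5,0.4,1587
R_bonasus,SCLN,night,15.3,0.7,2020
R_bonasus,SCLS,day,9.8,0.5,637
R_bonasus,SCLS,night,13.0,0.5,1154
R_bonasus,SINJ,day,10.1,0.6,954
R_bonasus,SINJ,night,18.0,0.9,790
R_bonasus,SISO,day,8.9,0.3,1784
R_bonasus,SISO,night,8.4,0.3,869
R_bonasus,SIWP,day,6.9,0.4,664
R_bonasus,SIWP,night,6.0,0.7,239
A_narinari,IR16,day,16.2,0.3,5011
A_narinari,IR16,night,20.1,0.2,10798
A_narinari,SCLN,day,8.0,0.2,3969
A_narinari,SCLN,night,9.3,0.2,4228
A_narinari,SCLS,day,11.0,0.4,1090
A_narinari,SCLS,night,10.7,0.4,1658
A_narinari,SINJ,day,42.9,0.2,73262
A_narinari,SINJ,night,32.5,0.2,47383
A_narinari,SISO,day,11.7,0.1,20423
A_narinari,SISO,night,9.5,0.1,12569
A_narinari,SIWP,day,4.0,0.1,4022
A_narinari,SIWP,night,3.6,0.1,2603
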