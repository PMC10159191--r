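species,receiver_id,n_detections,unique_tags
R_brasiliensis,IR16,35610,2
R_brasiliensis,SCLN,51,1
R_brasiliensis,SCLS,115,1
R_brasiliensis,SINJ,51,2
R_brasiliensis,SISO,127,3
R_brasiliensis,SIWP,11,2
R_bonasus,IR16,2779,10
R_bonasus,SCLN,3607,10
R_bonasus,SCLS,1791,9
R_bonasus,SINJ,1744,11
R_bonasus,SISO,2653,13
R_bonasus,SIWP,903,13
A_narinari,IR16,15809,16
A_narinari,SCLN,8197,16
A_narinari,SCLS,2748,16
A_narinari,SINJ,120645,20
A_narinari,SISO,32992,18
A_narinari,SIWP,6625,18
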