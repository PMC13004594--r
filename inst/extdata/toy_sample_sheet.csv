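sample_id,receptor,condition,pair_id,run_batch
MC01,ADORA1,media_control,,r1
MC02,ADORA1,media_control,,r1
VC_P1,ADORA1,vehicle_control,P1,r1
AG_P1,ADORA1,agonist,P1,r1
VC_P2,ADORA1,vehicle_control,P2,r1
AG_P2,ADORA1,agonist,P2,r1
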