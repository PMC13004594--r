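sample_id,assay_id,card,cq,amp_score,cq_conf
MC01,mir-A,A,Undetermined,,
MC02,mir-A,A,Undetermined,,
VC_P1,mir-A,A,25.0,1.30,0.95
AG_P1,mir-A,A,24.0,1.30,0.95
VC_P2,mir-A,A,25.2,1.30,0.95
AG_P2,mir-A,A,24.2,1.30,0.95
MC01,mir-B,A,Undetermined,,
MC02,mir-B,A,Undetermined,,
VC_P1,mir-B,A,27.0,1.25,0.95
AG_P1,mir-B,A,35.0,1.20,0.95
VC_P2,mir-B,A,27.5,1.25,0.95
AG_P2,mir-B,A,28.0,1.25,0.70
MC01,mir-C,B,30.0,1.40,0.96
MC02,mir-C,B,30.5,1.40,0.96
VC_P1,mir-C,B,33.0,0.50,0.90
AG_P1,mir-C,B,Undetermined,,
VC_P2,mir-C,B,Undetermined,,
AG_P2,mir-C,B,Undetermined,,
MC01,mir-D,B,26.8,1.35,0.97
MC02,mir-D,B,27.2,1.35,0.97
VC_P1,mir-D,B,26.0,1.35,0.97
AG_P1,mir-D,B,25.5,1.35,0.97
VC_P2,mir-D,B,26.0,1.35,0.97
AG_P2,mir-D,B,25.5,1.35,0.97
MC01,mir-E,B,30.0,1.45,0.98
MC02,mir-E,B,30.0,1.45,0.98
VC_P1,mir-E,B,26.0,1.45,0.98
AG_P1,mir-E,B,25.0,1.45,0.98
VC_P2,mir-E,B,26.4,1.45,0.98
AG_P2,mir-E,B,25.2,1.45,0.98
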