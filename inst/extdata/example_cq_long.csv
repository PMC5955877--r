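sample,target,replicate,cq
s1,Orr1a0,1,21.42
s1,Orr1a0,2,21.55
s1,Rltr2aiap,1,23.10
s1,Rltr2aiap,2,23.18
s1,Actb,1,19.85
s1,Actb,2,19.78
s2,Orr1a0,1,22.01
s2,Orr1a0,2,22.12
s2,Rltr2aiap,1,23.77
s2,Rltr2aiap,2,23.69
s2,Actb,1,21.44
s2,Actb,2,21.52
s3,Orr1a0,1,20.88
s3,Orr1a0,2,20.94
s3,Rltr2aiap,1,22.51
s3,Rltr2aiap,2,22.60
s3,Actb,1,19.01
s3,Actb,2,Undetermined
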