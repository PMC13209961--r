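ligand_id,target_id,affinity,cnn_pose_score,cnn_affinity
ChEMBL3661566,VEGFR-2,-10.99,0.537,7.802
ChEMBL4790167,VEGFR-2,-10.28,0.875,7.894
ChEMBL3661571,VEGFR-2,-10.44,0.804,7.759
ChEMBL4171108,VEGFR-2,-10.14,0.896,8.176
ChEMBL2354367,VEGFR-2,-10.14,0.809,8.386
ChEMBL4581299,VEGFR-2,-11.12,0.879,7.467
ChEMBL3661578,VEGFR-2,-10.52,0.8671,7.804
ChEMBL3641531,VEGFR-2,-10.85,0.905,8.133
ChEMBL4092441,VEGFR-2,-9.55,0.7488,7.734
ChEMBL2170947,VEGFR-2,-9.11,0.878,8.273
ChEMBL3661581,VEGFR-2,-10.03,0.763,8.067
ChEMBL1459733,VEGFR-2,-9.98,0.922,7.120
ChEMBL3661565,VEGFR-2,-10.82,0.800,7.989
ChEMBL3318995,VEGFR-2,-10.11,0.597,7.962
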