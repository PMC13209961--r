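ligand_id,target_id,affinity,cnn_pose_score,cnn_affinity
ChEMBL3903973,EGFR,-8.06,0.791,7.780
ChEMBL4865595,EGFR,-8.11,0.880,7.755
ChEMBL59202,EGFR,-8.69,0.587,7.696
ChEMBL3657549,EGFR,-8.62,0.843,7.286
ChEMBL3984043,EGFR,-8.49,0.890,7.441
ChEMBL2216869,EGFR,-9.00,0.966,8.171
ChEMBL165023,EGFR,-8.49,0.889,7.323
ChEMBL5091998,EGFR,-8.00,0.911,7.268
ChEMBL2041238,EGFR,-9.05,0.835,7.528
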