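ligand_id,target_id,affinity,cnn_pose_score,cnn_affinity
ChEMBL5019511,PDGFRa,-10.36,0.804,7.725
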