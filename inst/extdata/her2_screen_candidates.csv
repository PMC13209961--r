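ligand_id,target_id,affinity,cnn_pose_score,cnn_affinity
ChEMBL3355044,HER2,-10.39,0.869,7.564
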