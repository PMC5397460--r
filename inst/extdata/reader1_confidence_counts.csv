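modality,score,malignant,benign
wb_spect,1,23,245
wb_spect,2,140,527
wb_spect,3,401,182
wb_spect,4,180,48
spectct_2d,1,15,914
spectct_2d,2,52,74
spectct_2d,3,198,12
spectct_2d,4,479,2
spectct_3d,1,13,906
spectct_3d,2,52,78
spectct_3d,3,194,16
spectct_3d,4,485,2
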