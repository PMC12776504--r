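subject_id,group,gender,age,lesion_side,time_since_stroke,fma_pre,fma_post
S002,ER,M,60,right,24,28,33
S005,SOC,F,51,right,31,19,28
S007,SOC,F,57,left,26,23,33
S008,ER,M,74,left,21,20,22
S009,SOC,F,64,right,27,24,33
S012,SOC,F,57,right,31,15,23
S013,ER,F,55,left,16,32,33
S015,SOC,M,72,right,32,31,31
S016,ER,M,39,right,36,13,25
S017,SOC,F,45,right,26,26,32
S018,ER,M,54,right,38,22,25
S020,SOC,F,69,right,18,26,28
S021,ER,M,65,right,20,31,34
S022,ER,F,53,left,29,23,27
S023,SOC,M,51,left,27,32,34
S024,SOC,M,73,left,38,24,29
S025,SOC,M,60,left,36,23,23
S026,ER,M,67,left,14,23,25
S028,SOC,F,49,left,28,23,23
S029,ER,F,67,left,38,21,25
S030,SOC,M,58,right,39,27,27
S031,SOC,M,63,left,31,21,26
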