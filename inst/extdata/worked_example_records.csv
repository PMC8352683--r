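gender,fever,ulcer,pain,aching_and_limp,nasal_congestion,diarrhea,bleeding,tumor,drowsiness,face_yellowing,disease
1,1,1,1,0,0,0,0,1,0,0,10111
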