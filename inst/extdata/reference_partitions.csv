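dataset,n_bands,calibration,validation,test
DS_Jopung,23,2070,690,690
DS_Superior,24,1865,621,622
DS_Jopung_Superior,27,3935,1312,1311
TS_Jopung,31,2848,949,949
TS_Superior,32,2385,795,795
TS_Jopung_Superior,25,5228,1743,1743
DS_Jinyulmi,32,3870,1290,1290
EWS_Jinyulmi,21,3576,1192,1192
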