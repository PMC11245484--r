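subject_id,condition,kss,pvt_ms
S01,fatigue,7,553
S02,fatigue,8,388
S03,fatigue,7,404
S04,fatigue,7,424
S05,fatigue,7,447
S06,fatigue,7,399
S07,fatigue,8,386
S08,fatigue,7,511
S09,fatigue,9,532
S10,fatigue,8,350
S11,fatigue,7,646
S12,fatigue,7,593
S01,non_fatigue,2,365
S02,non_fatigue,3,285
S03,non_fatigue,3,324
S04,non_fatigue,3,363
S05,non_fatigue,3,365
S06,non_fatigue,3,350
S07,non_fatigue,3,346
S08,non_fatigue,3,352
S09,non_fatigue,3,393
S10,non_fatigue,2,398
S11,non_fatigue,3,362
S12,non_fatigue,3,372
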