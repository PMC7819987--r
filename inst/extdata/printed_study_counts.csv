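cohort,quantity,count
development,patients,482
development,screened,1059
development,fuzzy_sign,212
development,expansion,307
development_matched,pairs,158
development_matched,sign_expanded,138
development_matched,nosign_expanded,71
validation,patients,160
validation,expansion,102
validation_matched,pairs,50
validation_matched,sign_expanded,44
validation_matched,nosign_expanded,22
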