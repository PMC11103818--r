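admission_id,patient_id,admit_ts,discharge_ts,via_er,icu_stay,age_years
A001,P001,2020-06-01T08:00,2020-06-05T14:00,TRUE,FALSE,64
A002,P002,2020-07-07T09:00,2020-07-16T11:00,FALSE,FALSE,71
A003,P003,2020-08-02T09:00,2020-08-06T10:00,TRUE,FALSE,45
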