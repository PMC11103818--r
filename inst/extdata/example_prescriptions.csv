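prescription_id,patient_id,drug_name,atc_code,dose_mg_per_day,route,start_ts,stop_ts,indication_kind,indication_focus,indication_specification,indication_free_text,setting
RX001,P001,amoxicillin/clavulanic acid,J01CR02,3000,intravenous,2020-06-01T10:30,2020-06-04T12:00,empirical,sepsis e.c.i.,,,er
RX002,P001,ciprofloxacin,J01MA02,1000,oral,2020-06-05T10:00,2020-06-08T20:00,targeted,UTI,complicated,,inpatient
RX003,P001,cefazolin,J01DB04,2000,intravenous,2020-06-01T07:00,2020-06-01T09:00,prophylaxis,,,,inpatient
RX004,P001,paracetamol,N02BE01,3000,oral,2020-06-01T10:00,2020-06-06T10:00,,,,,inpatient
RX005,P002,ceftriaxone,J01DD04,2000,intravenous,2020-07-10T09:00,2020-07-14T18:00,empirical,RTI,HAP,,inpatient
RX006,P002,piperacillin/tazobactam,J01CR05,13500,intravenous,2020-07-14T20:00,2020-07-17T12:00,targeted,RTI,HAP,,inpatient
RX007,P002,nitrofurantoin,J01XE01,100,oral,2020-07-17T15:00,2020-08-20T12:00,,,,,outpatient
RX008,P003,flucloxacillin,J01CF05,4000,intravenous,2020-08-02T11:00,,targeted,skin/soft tissue,,,inpatient
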