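patient_id,date,diagnosis_codes,contact_type
p1,2019-01-07,P76,gp_day
p1,2020-03-12,P76,gp_e_day
p1,2020-03-13,P76;P74,ooh_evening
p2,2019-06-03,P03,gp_day
p2,2020-05-04,P82,gp_day
p3,2019-02-11,P74,gp_evening
p3,2021-01-05,P74,gp_e_evening
p4,2020-04-06,P76,gp_day
p5,2018-11-19,P01,ooh_day
p6,2019-07-01,P86,gp_day
p7,2019-03-04,P79;P01,gp_day
p8,2019-09-02,P76,gp_day
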