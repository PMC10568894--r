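patient_id,gender,birth_year
p1,female,1990
p2,male,1980
p3,female,2000
p4,female,1975
p5,male,1995
p6,female,1960
p7,male,1999
p8,female,2003
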