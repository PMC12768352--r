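sample	group	gene	ct
s1	srGFP	eGFP	24.05
s2	srGFP	eGFP	23.85
s3	srGFP	eGFP	24.30
s4	eGFP_dsRNA	eGFP	24.737
s5	eGFP_dsRNA	eGFP	24.837
s6	eGFP_dsRNA	eGFP	24.737
s1	srGFP	HKG4	20.10
s2	srGFP	HKG4	19.80
s3	srGFP	HKG4	20.30
s4	eGFP_dsRNA	HKG4	20.00
s5	eGFP_dsRNA	HKG4	20.20
s6	eGFP_dsRNA	HKG4	19.90
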