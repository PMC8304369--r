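domain	model_length	ga_threshold	coverage_threshold
zf-C2H2	23	9.45	NA
HLH	54	14.00	NA
bZIP_1	65	20.10	NA
bZIP_2	50	17.40	NA
bZIP_AUREO	60	22.00	0.75
bZIP_CDD	55	20.00	0.50
AP2	57	16.50	NA
HMG_box	70	21.20	NA
Homeobox	57	17.90	NA
PHD	52	16.00	NA
CBFD_NFYB_HMF	92	24.00	NA
SNF2_N	390	26.10	NA
HSF_DNA-bind	99	22.30	NA
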