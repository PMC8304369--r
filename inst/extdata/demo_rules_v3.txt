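# Demonstration TAP family rule catalogue (version 3 rule dialect)
# family; domain; should       -> domain required for membership
# family; domain; should not   -> domain vetoes membership
# family; TF|TR|PT; class      -> TAP class of the family
C2H2; zf-C2H2; should
C2H2; TF; class
bHLH; HLH; should
bHLH; TF; class
bZIP; bZIP_1; should
bZIP; HLH; should not
bZIP; Homeobox; should not
bZIP; TF; class
bZIPAUREO; bZIP_AUREO; should
bZIPAUREO; HLH; should not
bZIPAUREO; Homeobox; should not
bZIPAUREO; TF; class
bZIPCDD; bZIP_CDD; should
bZIPCDD; HLH; should not
bZIPCDD; Homeobox; should not
bZIPCDD; TF; class
AP2/EREBP; AP2; should
AP2/EREBP; TF; class
HMG; HMG_box; should
HMG; TR; class
PHD; PHD; should
PHD; HMG_box; should not
PHD; TR; class
CCAAT_HAP5; CBFD_NFYB_HMF; should
CCAAT_HAP5; HMG_box; should not
CCAAT_HAP5; TF; class
SWI/SNF_SNF2; SNF2_N; should
SWI/SNF_SNF2; HMG_box; should not
SWI/SNF_SNF2; TR; class
HSF; HSF_DNA-bind; should
HSF; TF; class
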