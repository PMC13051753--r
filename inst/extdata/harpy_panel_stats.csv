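locus,n,n_alleles,ho,he,p_hwe,q_exclusion,i_identity
Hha01,24,2,0.2727,0.2410,1.000,0.1759,0.6121
Hha02,24,8,0.5000,0.8266,0.000,0.7517,0.0837
Hha03,24,5,0.5454,0.6797,0.003,0.5037,0.2176
Hha04,24,2,0.0454,0.0454,1.000,0.0420,0.9141
Hha05,24,8,0.5000,0.5549,0.231,0.4602,0.3149
Hha06,24,4,0.8636,0.6839,0.000,0.5438,0.1777
Hha08,24,4,0.2727,0.3541,0.218,0.3067,0.4545
Hha09,24,4,0.0909,0.4904,0.000,0.3990,0.3233
Hha12,24,3,0.3181,0.3689,0.225,0.2654,0.4595
Hha18,24,4,0.2272,0.2896,0.265,0.2684,0.5279
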