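subject	blood	rpe_choroid	retina
S1	71	44	45
S2	144	12	17
S3	205	70	41
Total	420	128	103
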