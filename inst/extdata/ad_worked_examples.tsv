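gene	snp	p_eqtl	p_gwas
RP11-385F7.1	rs9473119	2.67E-13	1.02E-8
AC012146.7	rs73976310	6.19E-31	6.50E-8
PRSS36	rs1549299	3.36E-18	6.87E-8
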