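allele	pseudo_seq
HLA-A02:01	VCQIDDQKER
HLA-A02:06	VCNIDDVAEA
HLA-A03:01	VCQMTDPKEA
HLA-A11:01	VNQIDDVKEA
HLA-A24:02	VCQLDDQKEA
HLA-B07:02	VCQKDDQKEA
HLA-B35:01	VCQIDDQKYS
HLA-B57:01	VCQIDDQSEA
HLA-B58:01	QCQIDDQKEA
HLA-C03:03	VCQIMDQKEA
HLA-C07:01	VCQIDNQKEA
HLA-C07:02	ICQHDVQKEA
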