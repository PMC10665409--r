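trait	sex	n_fids	n_obs	mean	sd	h2	h2_se	vp	ve
CC	female	1580	287063	19.6	3.7	0.11	0.01	14.2	11.7
CC	male	889	287111	12.1	2.9	0.10	0.02	8.9	6.9
rbar	female	1580	287063	0.00806	0.00187	0.06	0.01	0.0038	0.0031
rbar	male	889	287111	0.00101	0.00056	0.11	0.03	0.0004	0.0002
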