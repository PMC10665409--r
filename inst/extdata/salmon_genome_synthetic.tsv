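chrom	length_bp	centromere_bp	acrocentric
ssa1	174500000	87250000	false
ssa2	95480000	47740000	false
ssa3	105780000	52890000	false
ssa4	90540000	45270000	false
ssa5	92790000	46395000	false
ssa6	96060000	48030000	false
ssa7	68860000	34430000	false
ssa8	28860000	2e+06	true
ssa9	161280000	2e+06	true
ssa10	125880000	2e+06	true
ssa11	111870000	2e+06	true
ssa12	101680000	2e+06	true
ssa13	114420000	2e+06	true
ssa14	101980000	2e+06	true
ssa15	110670000	2e+06	true
ssa16	96490000	2e+06	true
ssa17	87490000	2e+06	true
ssa18	84080000	2e+06	true
ssa19	88110000	2e+06	true
ssa20	96850000	2e+06	true
ssa21	59820000	2e+06	true
ssa22	63820000	2e+06	true
ssa23	52460000	2e+06	true
ssa24	49350000	2e+06	true
ssa25	54390000	2e+06	true
ssa26	55990000	2e+06	true
ssa27	45310000	2e+06	true
ssa28	41470000	2e+06	true
ssa29	43050000	2e+06	true
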