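# Elemental data: atomic number, standard atomic weight (g/mol, CIAAW),
# mean excitation energy I (eV, ICRU Report 37 recommended values).
# gas = 1 for elements gaseous in their pure standard state (these receive the
# conventional 1.13x condensed-phase I adjustment inside compounds).
symbol	Z	A	I_eV	gas
H	1	1.008	19.2	1
He	2	4.0026	41.8	1
Li	3	6.94	40.0	0
Be	4	9.0122	63.7	0
B	5	10.81	76.0	0
C	6	12.011	78.0	0
N	7	14.007	82.0	1
O	8	15.999	95.0	1
F	9	18.998	115.0	1
Ne	10	20.180	137.0	1
Na	11	22.98977	149.0	0
Mg	12	24.305	156.0	0
Al	13	26.9815	166.0	0
Si	14	28.085	173.0	0
P	15	30.9738	173.0	0
S	16	32.06	180.0	0
Cl	17	35.45	174.0	1
Ar	18	39.948	188.0	1
K	19	39.0983	190.0	0
Ca	20	40.078	191.0	0
Fe	26	55.845	286.0	0
Cu	29	63.546	322.0	0
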