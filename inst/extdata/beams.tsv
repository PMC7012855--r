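# Photon beam qualities used for the film study.  HVLs in mm Al.
# effective_energy_keV is the monoenergetic energy matching the 1st-HVL
# attenuation coefficient; equiv_energy_keV is the tabulated equivalent energy
# used as abscissa in the LET tables (for Co-60 it is the mean of the two
# gamma lines, adopted verbatim; its nominal effective energy is 1250 keV).
name	tube_potential_kV	added_filter	hvl1_mm_al	hvl2_mm_al	effective_energy_keV	equiv_energy_keV
20kV	20	0.2794 mm Al	0.25	0.39	13.476	13.48
50kV	50	1.0668 mm Al	1.13	1.72	23.56	23.56
80kV	80	2.8702 mm Al	2.83	4.17	32.3	32.33
120kV	120	7.112 mm Al	6.53	8.36	47.93	47.93
160kV	160	5.2324 mm Al + 0.254 mm Cu	10.4	10.75	67.385	67.39
Co60	Co60	none	NA	NA	1250	1044.7
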