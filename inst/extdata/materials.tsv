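# Material registry.  composition lists element=atomic-percent pairs separated
# by ';' (normalised on load).  Film compositions are the manufacturer atomic
# percentages for the Gafchromic EBT3 and MD-V3 active layers and whole films.
# Active-layer density is not published; 1.20 g/cm^3 is a typical manufacturer
# value (all ratio results are density-independent).  I_eV = NA means the mean
# excitation energy is derived by Bragg additivity from the elements.
name	density_g_cm3	I_eV	composition
EBT3_active	1.20	NA	H=56.5;Li=0.6;C=27.4;N=0.3;O=13.3;Na=0.1;Al=1.6;S=0.1;Cl=0.1
EBT3_overall	1.20	NA	H=38.4;Li=0.1;C=43.7;O=17.7;Al=0.2
MDV3_active	1.20	NA	H=58.2;Li=0.6;C=27.7;N=0.4;O=11.7;Na=0.5;Al=0.3;S=0.1;Cl=0.6
MDV3_overall	1.20	NA	H=38.3;C=43.9;O=17.7
water	1.00	75.0	H=66.667;O=33.333
aluminium	2.699	166.0	Al=100
PMMA	1.19	74.0	H=53.333;C=33.333;O=13.333
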