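# Density of aqueous glycine solutions at ~22 C as a function of composition.
# Computed from the literature apparent-molar-volume correlation
#   phiV(m) = 43.2 + 0.85 m  [cm^3/mol], m = molality (mol glycine / kg water),
# with water density 0.9977 g/cm^3 at 22 C; consistent with handbook
# densities of glycine-water mixtures to ~25 C within ~0.1%.
# Columns: conc_g_per_kg = g glycine per kg water; x_gly = mass fraction;
#          density_g_cm3 = solution mass density.
conc_g_per_kg,x_gly,density_g_cm3
0.00,0.00000000,0.997700
15.01,0.01479191,1.003991
30.03,0.02915261,1.010107
45.04,0.04310066,1.016053
60.06,0.05665361,1.021830
75.07,0.06982801,1.027443
90.08,0.08263950,1.032893
105.10,0.09510288,1.038186
120.11,0.10723213,1.043322
135.13,0.11904053,1.048306
150.14,0.13054063,1.053140
165.15,0.14174435,1.057828
180.17,0.15266301,1.062371
195.18,0.16330735,1.066773
210.20,0.17368757,1.071037
225.21,0.18381339,1.075165
240.22,0.19369404,1.079160
255.24,0.20333833,1.083025
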