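# Refractive index of aqueous glycine solutions at ~22 C (sodium D line),
# from the Lorentz-Lorenz/Clausius-Mossotti mixture rule with the
# literature molar refraction of glycine R_m = 16.43 cm^3/mol (specific
# refraction 0.2189 cm^3/g; dilute-limit dn/dc ~ 0.18 mL/g) and water
# n = 1.3330, rho = 0.9977 g/cm^3. Densities from the packaged density
# table.
# Columns: x_gly = mass fraction; refractive_index; density_g_cm3.
x_gly,refractive_index,density_g_cm3
0.05,1.342010,1.018994
0.10,1.351114,1.040261
0.15,1.360223,1.061265
0.20,1.369218,1.081691
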