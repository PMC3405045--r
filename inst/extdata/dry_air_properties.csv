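# Dry air at 1 atm: engineering property-table values used as the
# independent oracle for the package's air-property correlations.
# temp_c: air temperature (degC); k: thermal conductivity (W/m/K);
# nu: kinematic viscosity (m^2/s)
temp_c,k,nu
0,0.02436,1.338e-5
10,0.02512,1.426e-5
20,0.02587,1.516e-5
30,0.02662,1.608e-5
40,0.02735,1.702e-5
50,0.02808,1.798e-5
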