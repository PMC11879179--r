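id,year,lon,lat,temperature_c,nauplii_m3,cladocera_m3,copepods_m3,bluefin_m3
SYN01,2020,4.15922,40.2098,25.1466,426.648,0,690.624,0.317345
SYN02,2020,4.2483,38.404,24.0389,909.606,233.391,167.412,0.419731
SYN03,2020,1.64456,39.971,24.3835,1244,9.27719,186.046,0.607848
SYN04,2020,3.82179,40.1152,25.158,204.761,12.4436,74.3199,0.0962121
SYN05,2020,3.06698,39.3732,25.2451,378.55,2067.2,288.046,0
SYN06,2020,2.57638,40.1573,23.7177,410.294,226.395,147.346,0.0277745
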