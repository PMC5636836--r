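species,group,length_kind,form,length_scale,f_coef,f_extra,f_exp,f_a,f_b,f_c,m_coef,m_extra,m_exp,m_a,m_b,m_c,printed_f_coef,printed_f_extra,mean_length_cm,sd_length_cm,min_length_cm,max_length_cm,mean_mass_kg,sd_mass_kg,min_mass_kg,max_mass_kg,energy_density_kcal_g,mass_assumed
sevengill_shark,predator,total_length,quadratic,1,,,,0.003,-0.42,19.501,,,,0.002,-0.22,8.803,,,208,35,105,270,42.0,22.0,2.8,88.0,,FALSE
fur_seal,mammal,none,none,,,,,,,,,,,,,,,,,,,,2.1,1.3,0.7,4.0,2.5,FALSE
other_mammal,mammal,none,none,,,,,,,,,,,,,,,,,,,,2.1,1.3,0.7,4.0,2.4,FALSE
gummy_shark,shark,total_length,power,10,9.3e-10,1.07,3.21,,,,4.21e-9,1.016,2.976,,,,9.3e-30,1.07,74,20,28,143,1.8,1.6,0.1,11.5,1.5,FALSE
school_shark,shark,total_length,power,10,9.3e-10,1.07,3.21,,,,4.21e-9,1.016,2.976,,,,9.3e-30,1.07,66,16,31,113,1.2,0.8,0.1,5.2,1.5,FALSE
dogshark,shark,total_length,power,1,2.286120324e-05,1,2.6,,,,,,,,,,0.05,1000,54,11,19,94,0.73,0.5,0.03,4.2,1.5,FALSE
unidentified_shark,shark,none,none,,,,,,,,,,,,,,,,,,,,1.2433333333,0.9666666667,0.03,11.5,1.5,TRUE
eagle_ray,batoid,disc_width,power,1,2.76e-05,1,2.9,,,,,,,,,,,,81,14,70,110,9.1,5.8,0.9,48.6,1.1,FALSE
melbourne_skate,batoid,disc_width,quadratic,1,,,,0.005,-0.29,4.65,,,,,,,,,87,29,33,196,18.2,17.7,0.1,124.6,1.1,FALSE
banded_stingaree,batoid,disc_width,quadratic,1,,,,0.002,-0.03,0.14,,,,,,,,,18,4,9,30,0.3,0.2,0.03,1.1,1.1,FALSE
unidentified_batoid,batoid,none,none,,,,,,,,,,,,,,,,,,,,9.2,7.9,0.03,124.6,1.1,TRUE
elephantfish,chimaera,total_length,power,10,7.54e-10,1,3.3,,,,6.3e-11,1,3.7,,,,,,73,9,45,100,2.5,1.2,0.4,7.3,1.0,FALSE
teleosts,teleost,none,none,,,,,,,,,,,,,,,,,,,,0.8,0,0.8,0.8,1.5,FALSE
cephalopods,cephalopod,none,none,,,,,,,,,,,,,,,,,,,,0.7,0,0.7,0.7,1.5,FALSE
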