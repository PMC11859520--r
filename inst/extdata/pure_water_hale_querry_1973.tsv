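# Pure-water inherent optical properties, 300-1000 nm
# mu_a derived from the Hale & Querry (1973) imaginary refractive index
#   (mu_a = 4*pi*k/lambda); mu_s from the molecular scattering law
#   0.0037*(450/lambda)^4.32.
# units: m^-1
# columns: wavelength_nm mu_a_m mu_s_m
wavelength_nm	mu_a_m	mu_s_m
300	0.670206	0.0213263
325	0.41759	0.0150919
350	0.233375	0.0109574
375	0.117286	0.00813326
400	0.0584336	0.00615433
425	0.0384383	0.0047363
450	0.0284838	0.0037
475	0.0247359	0.0029293
500	0.0251327	0.00234709
525	0.0315954	0.00190104
550	0.044782	0.00155494
575	0.0786764	0.00128326
600	0.228289	0.00106774
625	0.279476	0.000895114
650	0.317059	0.000755604
675	0.415156	0.00064193
700	0.601391	0.000548601
725	1.58596	0.000471433
750	2.61381	0.000407207
775	2.39977	0.000353424
800	1.9635	0.000308128
825	2.77222	0.000269773
850	4.3317	0.000237132
875	5.61537	0.000209221
900	6.78584	0.000185247
925	14.4004	0.000164569
950	38.7573	0.000146661
975	44.8523	0.000131093
1000	36.3168	0.000117511
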