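id,rt,name,formula,adduct,theoretical_mz,measured_mz,error_ppm,fragments,plasma,cerebrum,class
E1,0.92,Aucubin,C15H22O9,[M-H]-,345.1191,345.1188,-0.87,299.1147;179.0565;137.0609;119.0446;113.0248;101.0247;89.0249,-,-,terpenoid
E2,6.98,Glucoaurantio-obtusin,C23H24O12,[M-H]-,491.1195,491.1200,1.02,476.1010;461.0737;433.0784;329.0680;313.0380;299.0222;285.0410;270.0174;242.0224,-,-,anthraquinone
E3,9.16,Forsythoside A,C29H36O15,[M-H]-,623.1981,623.1984,0.48,461.1665;443.1542;179.0351;135.0452,-,-,phenylethanoid glycoside
E4,8.25,Tenuifoliside C,C35H44O19,[M-H]-,767.2404,767.2398,-0.78,529.1556;341.1987;325.0892;295.0818;265.0721;237.0764;223.0617;205.0507,-,-,oligosaccharide
E5,20.29,Jaeschkeanadiol,C15H24O,[M+H-H2O]+,203.1794,203.1828,16.74,175.1495;161.1329;147.1176;133.1037;119.0866;105.0708;91.0547;81.0725,-,-,terpenoid
E6,23.52,Ursolic acid,C30H48O3,[M+H]+,457.3676,457.3677,0.22,439.3579;411.3607;393.3513;249.1352;203.1791;191.1795,-,-,terpenoid
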