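id,rt,name,parent,chain,formula,adduct,theoretical_mz,measured_mz,error_ppm,fragments,class
M1,0.73,Caffeic acid-2O,Caffeic acid,-2O,C9H8O2,[M-H]-,147.0452,147.0454,1.50,145.0497;103.0576;89.0246,phenolic acid
M2,0.76,Ferulic acid+2H,Ferulic acid,+2H,C10H12O4,[M+H]+,197.0808,197.0805,-1.77,179.0718;161.0596;151.0388;135.0446;133.0648;105.0692;91.0540,phenolic acid
M3,0.82,Protocatechuic acid+SO3+CH3,Protocatechuic acid,+SO3+CH2,C8H8O7S,[M-H]-,246.9918,246.9918,-0.07,167.0354;152.0118;123.0453;108.0220,phenolic acid
M4,0.86,Caffeic acid+SO3+2H,Caffeic acid,+SO3+2H,C9H10O7S,[M-H]-,261.0075,261.0074,-0.25,217.0182;181.0516;137.0614,phenolic acid
M5,1.00,Caffeic acid+2H,Caffeic acid,+2H,C9H10O4,[M-H]-,181.0506,181.0507,0.23,163.0408;135.0457;119.0507,phenolic acid
M6,1.01,Protocatechuic acid-CO2+SO3,Protocatechuic acid,-CO2+SO3,C6H6O5S,[M-H]-,188.9863,188.9865,1.18,109.0310;91.0192,phenolic acid
M7,1.25,Ferulic acid-CH2,Ferulic acid,-CH2,C9H8O4,[M+H]+,181.0495,181.0501,3.08,163.0391;145.0274;141.0728;135.0449;117.0344;105.0701;89.0382,phenolic acid
M8,1.25,Caffeic acid+C6H8O6,Caffeic acid,+C6H8O6,C15H16O10,[M-H]-,355.0671,355.0675,1.31,179.0358;135.0457,phenolic acid
M9,1.35,Caffeic acid+SO3,Caffeic acid,+SO3,C9H8O7S,[M-H]-,258.9918,258.9924,2.45,179.0354;135.0456,phenolic acid
M10,1.39,Caffeic acid+CH2,Caffeic acid,+CH2,C10H10O4,[M-H]-,193.0506,193.0509,1.15,178.0255;134.0379,phenolic acid
M11,1.42,Ferulic acid+SO3,Ferulic acid,+SO3,C10H10O7S,[M-H]-,273.0075,273.0073,-0.45,193.0512;178.0279;149.0615;134.0380,phenolic acid
M12,1.49,Caffeic acid+SO3+CH2,Caffeic acid,+SO3+CH2,C10H10O7S,[M-H]-,273.0075,273.0073,-0.54,193.0512;178.0274;149.0609;134.0377,phenolic acid
M13,1.62,Caffeic acid-O,Caffeic acid,-O,C9H8O3,[M-H]-,163.0401,163.0399,-0.90,145.8898;119.0507,phenolic acid
M14,1.67,Ferulic acid-CH2-O,Ferulic acid,-CH2-O,C9H8O3,[M-H]-,163.0401,163.0399,-1.27,119.0510;93.1455,phenolic acid
M15,1.67,Caffeic acid+SO3-O,Caffeic acid,+SO3-O,C9H8O6S,[M-H]-,242.9969,242.9965,-1.60,163.0410;119.0508,phenolic acid
M16,1.93,Ferulic acid+C6H8O6,Ferulic acid,+C6H8O6,C16H18O10,[M-H]-,369.0827,369.0820,-2.08,193.0510;178.0271;134.0377,phenolic acid
M17,2.15,Zedoalactone C+2H,Zedoalactone C,+2H,C15H24O4,[M+H]+,269.1747,269.1735,-4.63,251.1648;233.1556;215.1459;203.1461,terpenoid
M18,4.08,Ferulic acid+CH2+2H,Ferulic acid,+CH2+2H,C11H14O4,[M+H]+,211.0965,211.0964,-0.62,181.1248;179.0670;149.0248;131.0855;115.0516;105.0738;91.0540,phenolic acid
M19,4.45,Baicalein-O+2H,Baicalein,-O+2H,C15H12O4,[M+H]+,257.0808,257.0801,-2.81,163.0395;151.1130;135.0441;123.0439,flavonoid
M20,6.09,Oroxindin+O,Oroxindin,+O,C22H20O12,[M+H]+,477.1028,477.1024,-0.75,301.0705,flavonoid
M21,6.11,Baicalin+C6H8O6,Baicalin,+C6H8O6,C27H26O17,[M-H]-,621.1097,621.1095,-0.37,445.0774;269.0457,flavonoid
M22,6.12,Norwogonin+C6H8O6,Norwogonin,+C6H8O6,C21H18O11,[M-H]-,445.0776,445.0755,-4.85,269.0455,flavonoid
M23,6.16,Glychionide A+C6H8O6,Glychionide A,+C6H8O6,C27H26O17,[M-H]-,621.1097,621.1104,1.05,445.0779;269.0459,flavonoid
M24,6.19,Baicalin+2O+2H,Baicalin,+2O+2H,C21H20O13,[M+H]+,481.0977,481.0975,-0.27,305.0663;290.0445,flavonoid
M25,6.37,Oroxindin+C6H8O6,Oroxindin,+C6H8O6,C28H28O17,[M+H]+,637.1399,637.1416,2.54,461.1085;285.0757,flavonoid
M26,6.44,Baicalin+C6H8O6+CH2,Baicalin,+C6H8O6+CH2,C28H28O17,[M-H]-,635.1254,635.1253,-0.17,459.0914;283.0619;268.0382,flavonoid
M27,6.49,Ferulic acid-O+2H,Ferulic acid,-O+2H,C10H12O3,[M+H]+,181.0859,181.0866,3.62,151.0371;137.0577;123.0797;107.0866;105.0356;89.0392,phenolic acid
M28,6.77,Dihydrooroxylin A+C6H8O6,Dihydrooroxylin A,+C6H8O6,C22H22O11,[M-H]-,461.1089,461.1096,1.41,285.0786;270.0537;252.0435,flavonoid
M29,6.79,DiosMetin 7-O-beta-D-glucuronide+C6H8O6,DiosMetin 7-O-beta-D-glucuronide,+C6H8O6,C28H28O18,[M+H]+,653.1348,653.1369,3.20,477.1042;301.0715,flavonoid
M30,7.25,Tectoridin-CH2,Tectoridin,-CH2,C21H20O11,[M-H]-,447.0933,447.0939,1.30,271.0608;256.0383,flavonoid
M31,7.33,Baicalin+CH2+O,Baicalin,+CH2+O,C22H20O12,[M-H]-,475.0882,475.0879,-0.72,299.0570;284.0351,flavonoid
M32,7.95,Skullcapflavone I+C6H8O6,Skullcapflavone I,+C6H8O6,C23H22O12,[M+H]+,491.1184,491.1209,5.17,315.0875;300.0621;285.0344,flavonoid
M33,8.02,Wogonin+C6H8O6,Wogonin,+C6H8O6,C22H20O11,[M-H]-,459.0933,459.0938,1.04,283.0613;268.0382,flavonoid
M34,8.06,Baicalin+CH2,Baicalin,+CH2,C22H20O11,[M-H]-,459.0933,459.0930,-0.66,283.0620;268.0386,flavonoid
M35,8.24,Glychionide A+CH2,Glychionide A,+CH2,C22H20O11,[M-H]-,459.0933,459.0924,-1.91,283.0615;268.0380;240.0427,flavonoid
M36,8.45,Glychionide A-C6H8O6-O,Glychionide A,-C6H8O6-O,C15H10O4,[M+H]+,255.0652,255.0654,0.99,199.0734;181.1005;153.0183,flavonoid
M37,8.50,Glychionide A-O,Glychionide A,-O,C21H18O10,[M-H]-,429.0827,429.0811,-3.71,253.0512,flavonoid
M38,8.64,Baicalein+CH2+O,Baicalein,+CH2+O,C16H12O6,[M+H]+,301.0707,301.0715,2.66,286.0472;183.9997;155.9957;127.0066,flavonoid
M39,8.68,Baicalein+2H,Baicalein,+2H,C15H12O5,[M+H]+,273.0758,273.0749,-3.06,229.0489;168.8711,flavonoid
M40,8.69,Viscidulin II+CH2,Viscidulin II,+CH2,C18H16O7,[M+H]+,345.0969,345.0965,0.00,330.0717;312.0627;284.0689;266.0647,flavonoid
M41,8.71,Chrysin-7-O-glucuronide-C6H8O6+SO3,Chrysin-7-O-glucuronide,-C6H8O6+SO3,C15H10O7S,[M-H]-,333.0075,333.0088,3.95,253.0515;225.0562,flavonoid
M42,9.03,Norwogonin-O,Norwogonin,-O,C15H10O4,[M+H]+,255.0652,255.0659,2.72,227.0705;209.0576;199.0745;181.0635;153.0697,flavonoid
M43,9.06,DiosMetin 7-O-beta-D-glucuronide-O,DiosMetin 7-O-beta-D-glucuronide,-O,C22H20O11,[M-H]-,459.0933,459.0934,0.24,283.0620;268.0387;175.0253,flavonoid
M44,9.12,Baicalin-O,Baicalin,-O,C21H18O10,[M-H]-,429.0827,429.0841,3.17,253.0509,flavonoid
M45,9.20,Viscidulin II-O,Viscidulin II,-O,C17H14O6,[M+H]+,315.0863,315.0861,-0.53,300.0435;285.0328;269.0952,flavonoid
M46,9.21,Oroxindin+CH2+O,Oroxindin,+CH2+O,C23H22O12,[M+H]+,491.1184,491.1181,-0.70,315.0863;300.0624;285.0403,flavonoid
M47,9.48,Methyl eugenol-2CH2,Methyl eugenol,-2CH2,C9H10O2,[M+H]+,151.0754,151.0747,-4.19,107.0857;91.0542,phenylpropanoid
M48,9.57,DiosMetin 7-O-beta-D-glucuronide+CH2,DiosMetin 7-O-beta-D-glucuronide,+CH2,C23H22O12,[M+H]+,491.1184,491.1193,1.83,315.0871;300.0621,flavonoid
M49,9.81,Oroxylin A+SO3,Oroxylin A,+SO3,C16H12O8S,[M-H]-,363.0180,363.0186,1.57,283.0615;268.0381,flavonoid
M50,9.85,Wogonin+SO3,Wogonin,+SO3,C16H12O8S,[M-H]-,363.0180,363.0184,1.17,283.0620;268.0386,flavonoid
M51,10.27,Wogonin+O,Wogonin,+O,C16H12O6,[M+H]+,301.0707,301.0713,2.27,286.0496;255.1266;145.0174;127.0064,flavonoid
M52,10.76,beta-Asarone-2CH2,beta-Asarone,-2CH2,C10H12O3,[M+H]+,181.0859,181.0864,2.71,139.0753;135.0810;107.0866,phenylpropanoid
M53,11.09,Methyl eugenol-2CH2,Methyl eugenol,-CH2,C10H12O2,[M+H]+,165.0910,165.0912,1.11,137.0958;121.0648;119.0853;107.0492;91.0543,phenylpropanoid
M54,11.63,beta-Asarone-CH2,beta-Asarone,-CH2,C11H14O3,[M+H]+,195.1016,195.1022,3.07,163.0390;133.0315;121.1020;91.0529,phenylpropanoid
M55,11.88,alpha-Asarone-2CH2,alpha-Asarone,-2CH2,C10H12O3,[M+H]+,181.0859,181.0862,1.53,139.0732;135.0797;107.0847,phenylpropanoid
M56,12.42,Oroxylin A+O,Oroxylin A,+O,C16H12O6,[M+H]+,301.0707,301.0704,-0.87,283.0598;268.0353;240.0409;227.0692,flavonoid
M57,12.53,Wogonin+2H,Wogonin,+2H,C16H14O5,[M+H]+,287.0914,287.0920,2.23,183.0283;175.0145;168.0052;159.0230;131.0498,flavonoid
M58,14.02,Methyl eugenol+2H,Methyl eugenol,+2H,C11H16O2,[M+H]+,181.1223,181.1226,1.66,123.0801;91.0548,phenylpropanoid
M59,14.04,Dihydrooroxylin A+CH2,Dihydrooroxylin A,+CH2,C17H16O5,[M+H]+,301.1071,301.1072,0.59,286.9927;283.0514;255.1261,flavonoid
M60,19.96,Obtusifolin+CH2,Obtusifolin,+CH2,C17H14O5,[M+H]+,299.0914,299.0914,0.16,283.0485;269.0814;250.9921;226.0585,anthraquinone
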