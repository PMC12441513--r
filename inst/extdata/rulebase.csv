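rule_id,class,polarity,kind,value,series_count,tolerance,weight
fla_glca_loss,flavonoid,negative,neutral_loss,176.032088,1,0.01,1
fla_glc_loss,flavonoid,negative,neutral_loss,162.052823,1,0.01,1
fla_ch3_loss,flavonoid,negative,neutral_loss,15.023475,1,0.01,1
fla_h2o_loss,flavonoid,negative,neutral_loss,18.010565,1,0.01,1
fla_co_loss,flavonoid,negative,neutral_loss,27.994915,1,0.01,1
fla_ch2o_loss,flavonoid,negative,neutral_loss,30.010565,1,0.01,1
fla_o_loss,flavonoid,negative,neutral_loss,15.994915,1,0.01,1
fla_rda_ion,flavonoid,negative,diagnostic_ion,169.0661,1,0.01,2
fla_aglycone_ion,flavonoid,negative,diagnostic_ion,269.0455,1,0.01,2
iri_diag_179,terpenoid,negative,diagnostic_ion,179.0565,1,0.01,2
iri_diag_89,terpenoid,negative,diagnostic_ion,89.0249,1,0.01,2
iri_ch2o_loss,terpenoid,negative,neutral_loss,30.010565,1,0.01,1
iri_o_loss,terpenoid,negative,neutral_loss,15.994915,1,0.01,1
iri_glc_loss,terpenoid,negative,neutral_loss,162.052823,1,0.01,1
ses_ch2_ladder,terpenoid,positive,serial_loss,14.015650,3,0.02,2
tri_diag_249,terpenoid,positive,diagnostic_ion,249.1352,1,0.01,2
tri_diag_203,terpenoid,positive,diagnostic_ion,203.1791,1,0.01,2
tri_diag_191,terpenoid,positive,diagnostic_ion,191.1795,1,0.01,2
tri_glc_loss,terpenoid,negative,neutral_loss,162.052823,1,0.01,1
tri_ara_loss,terpenoid,negative,neutral_loss,146.057909,1,0.01,1
php_ch3_loss,phenylpropanoid,positive,neutral_loss,15.023475,1,0.01,1
php_ch2o_loss,phenylpropanoid,positive,neutral_loss,30.010565,1,0.01,1
php_h2o_loss,phenylpropanoid,positive,neutral_loss,18.010565,1,0.01,1
php_co2_loss,phenylpropanoid,positive,neutral_loss,43.989829,1,0.01,1
php_glc_loss,phenylpropanoid,positive,neutral_loss,162.052823,1,0.01,1
php_rut_loss,phenylpropanoid,positive,neutral_loss,308.110732,1,0.01,1
alk_diag_160,alkaloid,positive,diagnostic_ion,160.0757,1,0.01,2
alk_diag_170,alkaloid,positive,diagnostic_ion,170.0966,1,0.01,2
alk_diag_144,alkaloid,positive,diagnostic_ion,144.0808,1,0.01,2
ant_ch3_loss,anthraquinone,negative,neutral_loss,15.023475,1,0.01,1
ant_ch3_serial,anthraquinone,negative,serial_loss,15.023475,2,0.01,2
ant_co_loss,anthraquinone,negative,neutral_loss,27.994915,1,0.01,1
ant_o_loss,anthraquinone,negative,neutral_loss,15.994915,1,0.01,1
ant_glc_loss,anthraquinone,negative,neutral_loss,162.052823,1,0.01,1
peg_diag_179,phenylethanoid glycoside,negative,diagnostic_ion,179.0351,1,0.01,2
peg_diag_135,phenylethanoid glycoside,negative,diagnostic_ion,135.0452,1,0.01,2
peg_glc_loss,phenylethanoid glycoside,negative,neutral_loss,162.052823,1,0.01,1
oli_acyl_loss,oligosaccharide,negative,neutral_loss,238.084124,1,0.01,1
oli_ch2o_serial,oligosaccharide,negative,serial_loss,30.010565,2,0.01,2
oli_o_loss,oligosaccharide,negative,neutral_loss,15.994915,1,0.01,1
pha_co2_loss,phenolic acid,negative,neutral_loss,43.989829,1,0.01,2
pha_h2o_loss,phenolic acid,negative,neutral_loss,18.010565,1,0.01,1
xan_h2o_loss,xanthone,positive,neutral_loss,18.010565,1,0.01,1
xan_co_loss,xanthone,positive,neutral_loss,27.994915,1,0.01,1
xan_ch3_loss,xanthone,positive,neutral_loss,15.023475,1,0.01,1
nap_h2o_loss,naphthopyrone,positive,neutral_loss,18.010565,1,0.01,1
nap_co_loss,naphthopyrone,positive,neutral_loss,27.994915,1,0.01,1
pht_h2o_loss,phthalein,positive,neutral_loss,18.010565,1,0.01,1
pht_co_loss,phthalein,positive,neutral_loss,27.994915,1,0.01,1
org_co2_loss,organic acid,negative,neutral_loss,43.989829,1,0.01,1
org_h2o_loss,organic acid,negative,neutral_loss,18.010565,1,0.01,1
ald_co_loss,aromatic aldehyde,positive,neutral_loss,27.994915,1,0.01,1
ald_h2o_loss,aromatic aldehyde,positive,neutral_loss,18.010565,1,0.01,1
dia_h2o_loss,diarylheptanoid,positive,neutral_loss,18.010565,1,0.01,1
dia_co_loss,diarylheptanoid,positive,neutral_loss,27.994915,1,0.01,1
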