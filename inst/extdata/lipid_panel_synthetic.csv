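# Illustrative (synthetic) target panel: sum-composition names with
# [M+H]+ m/z computed from the molecular formula monoisotopic mass.
# Not instrument-calibrated values.
"name","lipid_class","carbons","double_bonds","adduct","target_mz"
"PC 30:1","PC",30,1,"[M+H]+",704.5225
"PC 32:0","PC",32,0,"[M+H]+",734.5694
"PC 32:1","PC",32,1,"[M+H]+",732.5538
"PC 32:2","PC",32,2,"[M+H]+",730.5381
"PC 32:3","PC",32,3,"[M+H]+",728.5225
"PC 32:4","PC",32,4,"[M+H]+",726.5068
"PC 34:0","PC",34,0,"[M+H]+",762.6007
"PC 34:1","PC",34,1,"[M+H]+",760.5851
"PC 34:2","PC",34,2,"[M+H]+",758.5694
"PC 34:3","PC",34,3,"[M+H]+",756.5538
"PC 34:4","PC",34,4,"[M+H]+",754.5381
"PC 36:1","PC",36,1,"[M+H]+",788.6164
"PC 36:2","PC",36,2,"[M+H]+",786.6007
"PC 36:3","PC",36,3,"[M+H]+",784.5851
"PC 36:4","PC",36,4,"[M+H]+",782.5694
"PC 36:5","PC",36,5,"[M+H]+",780.5538
"PC 38:3","PC",38,3,"[M+H]+",812.6164
"PC 38:4","PC",38,4,"[M+H]+",810.6007
"PC 38:5","PC",38,5,"[M+H]+",808.5851
"PC 38:8","PC",38,8,"[M+H]+",802.5381
"PC 40:3","PC",40,3,"[M+H]+",840.6477
"PC 40:4","PC",40,4,"[M+H]+",838.632
"PC 40:5","PC",40,5,"[M+H]+",836.6164
"PC 40:6","PC",40,6,"[M+H]+",834.6007
"PC 40:9","PC",40,9,"[M+H]+",828.5538
"PE 34:0","PE",34,0,"[M+H]+",720.5538
"PE 34:1","PE",34,1,"[M+H]+",718.5381
"PE 34:2","PE",34,2,"[M+H]+",716.5225
"PE 34:3","PE",34,3,"[M+H]+",714.5068
"PE 36:0","PE",36,0,"[M+H]+",748.5851
"PE 36:1","PE",36,1,"[M+H]+",746.5694
"PE 36:3","PE",36,3,"[M+H]+",742.5381
"PE 36:4","PE",36,4,"[M+H]+",740.5225
"PE 38:6","PE",38,6,"[M+H]+",764.5225
"SM 34:1","SM",34,1,"[M+H]+",703.5749
"SM 36:1","SM",36,1,"[M+H]+",731.6062
"SM 36:2","SM",36,2,"[M+H]+",729.5905
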