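individual,farm,sex,body_mass_g,screened_fixes
LPD001,Baakensrug,Female,11685,4017
LPD002,Baakensrug,Female,11580,3587
LPD004,Baakensrug,Male,7425,4122
LPD010,Kamferskraal,Female,26167,4159
LPD011,Kamferskraal,Female,18400,3647
LPD013,Kamferskraal,Male,12560,3790
LPD015,Elandsfontein,Male,15125,3941
LPD016,Elandsfontein,Male,14870,3330
LPD017,Elandsfontein,Female,16638,3884
LPD048,Baakensrug,Male,9275,2577
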