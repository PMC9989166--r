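"animal_id","genotype","age_months","treatment","session","attack_duration_s"
"R1","SAMR1",7,"vehicle","m7_vehicle",6
"R2","SAMR1",7,"vehicle","m7_vehicle",8
"R3","SAMR1",7,"vehicle","m7_vehicle",7
"R4","SAMR1",7,"vehicle","m7_vehicle",9
"P1","SAMP8",7,"vehicle","m7_vehicle",10
"P2","SAMP8",7,"vehicle","m7_vehicle",12
"P3","SAMP8",7,"vehicle","m7_vehicle",11
"P4","SAMP8",7,"vehicle","m7_vehicle",13
"R1","SAMR1",7,"drug","m7_drug",4
"R2","SAMR1",7,"drug","m7_drug",6
"R3","SAMR1",7,"drug","m7_drug",3
"R4","SAMR1",7,"drug","m7_drug",7
"P1","SAMP8",7,"drug","m7_drug",6
"P2","SAMP8",7,"drug","m7_drug",8
"P3","SAMP8",7,"drug","m7_drug",9
"P4","SAMP8",7,"drug","m7_drug",9
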