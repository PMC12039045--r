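group,prescribed,registered
all,2048040,25455570
female,1360440,12709460
male,687600,12746120
age_0_19,30200,5582550
age_80_plus,179350,1288270
imd_most_deprived,468560,5025740
imd_least_deprived,315030,4517350
ethnicity_white,1660980,16863830
learning_disability,26810,145920
autism,31360,264610
all_no_diagnosis,614500,14977500
learning_disability_no_diagnosis,9780,83390
autism_no_diagnosis,6330,66980
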