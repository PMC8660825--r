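# Conservation-law / pool-total membership table (synthetic reconstruction).
# "1" as member_species denotes a constant offset (the CDK1 normalization).
total_name,member_species,stoichiometry
CDK1,1,1
CDK1,MPF,-1
CDK1,preMPF,-1
CDK1,p21:MPF,-1
CDK1_T,1,1
CyclinB_T,CyclinB,1
CyclinB_T,MPF,1
CyclinB_T,preMPF,1
CyclinB_T,p21:MPF,1
p21_T,p21,1
p21_T,p21:MPF,3
Cdc25_T,Cdc25,1
Cdc25_T,Cdc25P,1
Wee1_T,Wee1,1
Wee1_T,Wee1P,1
Plk1_T,Plk1,1
Plk1_T,Plk1P,1
Plk1_T,p53P:Plk1P,1
PP2A_T,PP2A,1
PP2A_T,PP2AP,1
APC_T,APC/C,1
APC_T,APC/CP,1
APC_T,APC/CP:Cdc20,1
APC_T,APC/CT:Cdh1,1
Cdc20_T,Cdc20,1
Cdc20_T,Cdc20P,1
Cdc20_T,APC/CP:Cdc20,1
Cdc20_T,Mad2:Cdc20P,1
Cdh1_T,Cdh1,1
Cdh1_T,Cdh1P,1
Cdh1_T,APC/CT:Cdh1,1
Emi1_T,Emi1,1
Emi1_T,Emi1P,1
Separase_T,Separase,1
Separase_T,Pttg1:Separase,1
Pttg1_T,Pttg1,1
Pttg1_T,Pttg1:Separase,1
p53_T,p53,1
p53_T,p53P,1
p53_T,p53P:Plk1P,1
Mad2_T,Mad2,1
Mad2_T,Mad2:Cdc20P,1
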