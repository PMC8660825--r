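species,value
CyclinB,0.0014138582510128128
MPF,0.015045419781767391
preMPF,0.17491785853101721
p21:MPF,0.0033937350065014163
p21,0.088533920718239303
Cdc25P,0.002651085710851766
Wee1P,0.005269669723228794
Cdc25,0.034389550106991386
Wee1,0.64376780431661329
PP2AP,0.056581447810104067
Plk1P,0.0019761179431492656
Plk1,0.17403156430527411
PP2A,0.44341855218989634
Emi1,0.33748500470401693
APC/C,0.40368867571102768
APC/CP,0.0011259521493273803
Cdc20,0.019435995399041214
Cdc20P,0.0010057148353487854
APC/CP:Cdc20,3.053369579781144e-07
Cdh1,0.74511277850496738
Cdh1P,0.0040741271135730532
APC/CT:Cdh1,0.74561656664055187
Separase,0.0035683798999975036
Pttg1,1.1116551694765555
Pttg1:Separase,0.39643162010000399
Emi1P,0.062514995295985198
ATM/ATR,0.2906841971186771
p53,0.24944366271815813
p53P,0.075430363454921531
p53P:Plk1P,0.013990902675028803
Mdm2,0.083607326528669201
Wip1,0.07077613680979096
Mad2,0.82922153601962845
Mad2:Cdc20P,0.10663630817263747
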