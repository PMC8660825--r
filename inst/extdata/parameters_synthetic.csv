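symbol,value
k_s1,0.010927496847301309
k_s5,0.00095021711715663558
k_s8,0.085519540544097203
k_s9,0.028506513514699065
k_s12,0.047510855857831782
k_s13,0.047510855857831782
k_s15,0.028506513514699065
k_s17,0.057013027029398131
k_s20,0.047510855857831782
k_s24,0.028506513514699065
k_s27,0.035953980574571116
k_s28,0.027269694528555578
k_s31,0.0044501331141774299
k_s32,0.0043055325983842692
k_s33,0.076017369372530855
k_s31.1,0.29636353616534589
k_s32.1,0.75474903200518528
k_f1,9.5021711715663546
k_r1,0.095021711715663565
k_f2, 1.900434234313271
k_f2.1,0.19954559460289345
k_r2,4.7510855857831773
k_r2.1,0.057013027029398131
k_f3,0.095021711715663565
k_r3,0.028506513514699065
k_f4,13.303039640192898
k_r4, 1.900434234313271
k_r4.1,0.047510855857831782
k_f5,0.095021711715663565
k_r5,18.922916666666669
k_f6p,4.7510855857831773
k_r6,0.19004342343132713
k_f7, 1.900434234313271
k_r7,0.28506513514699067
k_f8,9.5021711715663546
k_r8,0.28506513514699067
k_f9, 1.900434234313271
k_r9,0.66515198200964476
k_f10, 2.850651351469907
k_r10,3.8008684686265419
k_r10.1,0.047510855857831782
k_f11, 1.900434234313271
k_r11,0.19004342343132713
k_f12, 2.850651351469907
k_r12, 2.850651351469907
k_r12.1,0.095021711715663565
k_r12.2,0.47510855857831774
k_f13,0.95021711715663548
k_r13,0.28506513514699067
k_f14,9.5021711715663546
k_r14,0.095021711715663565
k_f16,0.19189849889676716
k_r16,0.36945725612912705
k_f17,4.7510855857831773
k_r17,0.23755427928915887
k_f18,95.021711715663542
k_r18p,0.14253256757349533
k_f19,4.7510855857831773
k_d1,0.0095021711715663568
k_d1.2, 2.850651351469907
k_d1.3,0.28506513514699067
k_d2.2, 2.850651351469907
k_d3.2, 2.850651351469907
k_d4.2, 2.850651351469907
k_d5,0.14253256757349533
k_d6.1,0.0062455848052254247
k_d6.3,0.28506513514699067
k_d7.1,0.019004342343132714
k_d8.1,0.019004342343132714
k_d8.3,0.47510855857831774
k_d9.1,0.028506513514699065
k_d9.3,0.047510855857831782
k_d10,0.095021711715663565
k_d11.1,0.047510855857831782
k_d11.3,0.47510855857831774
k_d12,0.076017369372530855
k_d12.3,0.095021711715663565
k_d13,0.095021711715663565
k_d15,0.047510855857831782
k_d17.1,0.047510855857831782
k_d17.3,0.95021711715663548
k_d18.1,0.047510855857831782
k_d18.3,0.47510855857831774
k_d19.3,0.19004342343132713
k_d20,0.047510855857831782
k_d21,0.047510855857831782
k_d24.1,0.019004342343132714
k_d24.2,0.95021711715663548
k_d25.2,0.95021711715663548
k_d27,0.10106867556619456
k_d27.1,6.7999999999999998
k_d28,0.075322163898799005
k_d28.1, 3.602492354467441
k_d29,0.16186162672416615
k_d29.1,1.9340781258471695
k_d30.1,0.47510855857831774
k_d31,0.15035900850213924
k_d31.1,0.62957522032312807
k_d32,0.89018995617592522
k_d33,0.095021711715663565
K_p53,              0.02
K_A1,               0.5
K_A2,               0.5
K_A3,0.093000774223278695
K_Cdc25P1,0.10000000000000001
K_Cdc25P2,0.20000000000000001
K_Cdc25,0.20000000000000001
K_Wee1,0.20000000000000001
K_Wee1P,              0.02
K_Plk1P1,0.10000000000000001
K_Plk1P2,0.10000000000000001
K_Plk1,0.20000000000000001
K_Cdc20P1,0.10000000000000001
K_Cdc20P2,0.20000000000000001
K_Cdc20,0.20000000000000001
K_CycB1,0.20000000000000001
K_CycB2,0.20000000000000001
K_MPF,0.20000000000000001
K_preMPF,0.20000000000000001
K_p21MPF,0.20000000000000001
K_APC20,0.20000000000000001
K_Pttg1,0.20000000000000001
K_PtSep,0.20000000000000001
K_Emi1,0.10000000000000001
K_Wee1f,0.050000000000000003
K_APC,0.050000000000000003
K_APP,0.050000000000000003
K_Cdh1,0.050000000000000003
K_APCH,0.10000000000000001
K_Cdh1P,0.050000000000000003
K_Sep,0.20000000000000001
K_Wip1,0.29662474054250354
K_MCD,              0.02
K_DDS,                 2
eps_MCD,                 3
Emi1_tot,0.40000000000000002
Sep_tot,0.40000000000000002
tau,1.6499999999999999
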