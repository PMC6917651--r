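drug_class,drug,prepulse,conc_uM,block_nav15,sem_nav15,block_nav15_b1,sem_nav15_b1,block_hsc_cm,sem_hsc_cm,p_b1_vs_nav15,p_hsc_vs_nav15,p_hsc_vs_b1
Ia,quinidine,standard,3,14,3,14,3,11,2,not significant (0.266),not significant (0.266),not significant (0.266)
Ia,quinidine,standard,10,35,3,31,3,28,2,not significant (0.114),not significant (0.114),not significant (0.114)
Ia,quinidine,standard,30,65,1,59,5,65,3,not significant (0.388),not significant (0.388),not significant (0.388)
Ia,ajmaline,standard,3,18,2,21,3,17,3,not significant (0.564),not significant (0.564),not significant (0.564)
Ia,ajmaline,standard,10,67,4,57,3,47,2,0.044,<0.001,0.055
Ia,ajmaline,standard,30,88,2,81,3,72,2,0.029,<0.001,0.083
Ib,lidocaine,standard,3,20,2,7,1,7,1,<0.001,<0.001,0.807
Ib,lidocaine,standard,10,31,3,19,2,12,1,<0.001,<0.001,0.003
Ib,lidocaine,standard,30,56,2,37,2,26,2,<0.001,<0.001,<0.001
Ib,lidocaine,standard,100,69,1,56,3,43,3,0.009,<0.001,0.005
Ib,lidocaine,standard,300,87,2,69,3,52,3,<0.001,<0.001,<0.001
Ib,lidocaine,standard,1000,89,2,74,3,72,2,0.001,<0.001,0.531
Ib,phenytoin,standard,3,11,1,3,1,4,1,<0.001,<0.001,0.362
Ib,phenytoin,standard,10,17,2,11,2,6,1,0.027,<0.001,0.027
Ib,phenytoin,standard,30,40,2,21,2,17,1,<0.001,<0.001,0.150
Ib,phenytoin,standard,100,59,2,36,4,33,2,<0.001,<0.001,0.449
Ib,phenytoin,standard,300,70,2,48,1,45,3,<0.001,<0.001,0.071
Ib,phenytoin,depolarized,3,27,3,16,5,11,2,0.03,<0.001,0.195
Ib,phenytoin,depolarized,10,50,2,38,5,39,4,not significant (0.209),not significant (0.209),not significant (0.209)
Ib,phenytoin,depolarized,100,76,2,58,5,58,2,0.002,0.002,0.934
Ic,flecainide,standard,3,33,3,28,3,25,2,not significant (0.058),not significant (0.058),not significant (0.058)
Ic,flecainide,standard,10,73,2,61,3,54,2,0.001,<0.001,0.031
Ic,flecainide,standard,30,89,1,89,1,83,2,not significant (0.012),not significant (0.012),not significant (0.012)
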