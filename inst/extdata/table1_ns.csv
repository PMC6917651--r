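drug,prepulse,n_nav15,n_nav15_b1,n_hsc_cm
quinidine,standard,8,7,12
ajmaline,standard,6,7,8
lidocaine,standard,7,10,11
phenytoin,standard,10,10,12
phenytoin,depolarized,5,5,8
flecainide,standard,16,14,15
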