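&FCI NORB=2,NELEC=2,MS2=0,
 ORBSYM=1,1,
 ISYM=1,
&END
 3.4917158729496711E-01   1   1   1   1
 1.0776425782774840E-18   2   1   1   1
 6.4625780402907909E-02   2   1   2   1
 3.4917158729496711E-01   2   2   1   1
 2.2428264861335897E-18   2   2   2   1
 3.4917158729496711E-01   2   2   2   2
-3.7935905810524906E-01   1   1   0   0
 3.7413550255306909E-18   2   1   0   0
-1.8973255567886935E-01   2   2   0   0
 2.8454580689205927E-01   0   0   0   0
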