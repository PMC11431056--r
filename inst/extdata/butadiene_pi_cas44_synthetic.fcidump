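&FCI NORB=4,NELEC=4,MS2=0,
 ORBSYM=1,1,1,1,
 ISYM=1,
&END
 3.1925067036556515E-01   1   1   1   1
-3.6465104573279319E-16   2   1   1   1
 6.4274852036130800E-02   2   1   2   1
 2.9816335540364913E-01   2   2   1   1
-2.1452538296513983E-16   2   2   2   1
 2.8427741727556732E-01   2   2   2   2
-3.0902893224794489E-02   3   1   1   1
 6.2317205875201351E-18   3   1   2   1
-2.0349469056312033E-02   3   1   2   2
 1.5465759430424320E-02   3   1   3   1
-7.8741291588552810E-17   3   2   1   1
 2.0746835194691726E-02   3   2   2   1
-3.8863352902959905E-17   3   2   2   2
-3.2024975122808410E-17   3   2   3   1
 3.1086885959323789E-02   3   2   3   2
 2.4342748296678932E-01   3   3   1   1
-2.8214160946526308E-16   3   3   2   1
 2.4823399783513633E-01   3   3   2   2
 7.0438183347748852E-03   3   3   3   1
-1.0460808756750301E-16   3   3   3   2
 2.6071016111978673E-01   3   3   3   3
 8.9049597206148103E-17   4   1   1   1
-1.5552035164812151E-02   4   1   2   1
 3.5894900287078712E-17   4   1   2   2
-2.7598432318824827E-17   4   1   3   1
 1.1391732422337380E-02   4   1   3   2
 1.1559555106476082E-17   4   1   3   3
 1.4806085865754891E-02   4   1   4   1
-4.5926260368708151E-02   4   2   1   1
 2.1859154249501490E-17   4   2   2   1
-3.0242314447610177E-02   4   2   2   2
 2.2984401144407508E-02   4   2   3   1
 7.5372179786648261E-18   4   2   3   2
 1.0468153660550971E-02   4   2   3   3
-4.8195615865078678E-18   4   2   4   1
 3.4158212426853150E-02   4   2   4   2
-9.4428485338884897E-17   4   3   1   1
 6.7975815778031662E-02   4   3   2   1
 4.5131431649735019E-17   4   3   2   2
-4.3862987639218472E-17   4   3   3   1
 5.1010141872969268E-02   4   3   3   2
-7.6390824627010756E-17   4   3   3   3
 3.1122396953279538E-03   4   3   4   1
 2.6665385405257130E-18   4   3   4   2
 1.0653456118834041E-01   4   3   4   3
 2.6451479792870530E-01   4   4   1   1
-1.3351667758783508E-16   4   4   2   1
 2.6211993596321814E-01   4   4   2   2
-3.5096058337075911E-03   4   4   3   1
 2.3577428768203619E-17   4   4   3   2
 2.5590364625143969E-01   4   4   3   3
 3.4901811862717156E-17   4   4   4   1
-5.2157922605470175E-03   4   4   4   2
 1.4122115643082910E-16   4   4   4   3
 2.5829850821692690E-01   4   4   4   4
-8.4387389380636768E-01   1   1   0   0
 5.8215251422366428E-16   2   1   0   0
-7.1320165742016461E-01   2   2   0   0
 4.5910000246310690E-17   3   1   0   0
 1.3263029601641641E-16   3   2   0   0
-5.4374646086569700E-01   3   3   0   0
-2.0742182058534841E-18   4   1   0   0
 6.9222406409048907E-17   4   2   0   0
-4.0034473302495395E-17   4   3   0   0
-5.1125170679199194E-01   4   4   0   0
 1.3060368594421106E+00   0   0   0   0
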