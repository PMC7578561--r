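date,outcome,control
2003-01-01,670,10318
2003-02-01,566,12094
2003-03-01,566,10253
2003-04-01,465,9253
2003-05-01,370,7665
2003-06-01,411,7742
2003-07-01,355,8016
2003-08-01,418,6760
2003-09-01,380,7495
2003-10-01,373,8336
2003-11-01,427,8248
2003-12-01,528,10736
2004-01-01,594,12948
2004-02-01,485,9856
2004-03-01,546,14540
2004-04-01,447,9492
2004-05-01,384,8348
2004-06-01,345,8534
2004-07-01,355,7329
2004-08-01,387,7068
2004-09-01,415,7309
2004-10-01,398,8023
2004-11-01,540,8283
2004-12-01,475,12536
2005-01-01,603,12736
2005-02-01,610,10875
2005-03-01,524,12468
2005-04-01,471,8971
2005-05-01,470,7950
2005-06-01,433,7386
2005-07-01,465,7064
2005-08-01,340,6965
2005-09-01,353,7740
2005-10-01,412,7404
2005-11-01,454,10611
2005-12-01,599,11100
2006-01-01,660,11512
2006-02-01,624,12107
2006-03-01,488,11262
2006-04-01,490,9725
2006-05-01,415,7511
2006-06-01,426,7577
2006-07-01,357,8312
2006-08-01,415,7309
2006-09-01,378,7851
2006-10-01,423,6905
2006-11-01,533,8813
2006-12-01,493,10451
2007-01-01,622,12928
2007-02-01,561,11515
2007-03-01,617,11109
2007-04-01,415,9604
2007-05-01,462,9221
2007-06-01,381,8069
2007-07-01,396,7000
2007-08-01,298,7380
2007-09-01,301,6381
2007-10-01,353,7873
2007-11-01,495,9607
2007-12-01,545,10388
2008-01-01,643,12480
2008-02-01,557,13672
2008-03-01,567,9929
2008-04-01,480,8525
2008-05-01,359,8271
2008-06-01,399,8499
2008-07-01,357,8089
2008-08-01,339,7424
2008-09-01,313,6638
2008-10-01,376,8199
2008-11-01,456,9137
2008-12-01,499,10719
2009-01-01,603,12806
2009-02-01,621,13030
2009-03-01,523,9459
2009-04-01,427,8431
2009-05-01,345,7959
2009-06-01,326,8055
2009-07-01,361,6194
2009-08-01,381,6899
2009-09-01,316,7100
2009-10-01,422,7464
2009-11-01,437,7896
2009-12-01,525,9804
2010-01-01,621,11712
2010-02-01,601,14665
2010-03-01,554,9732
2010-04-01,462,9440
2010-05-01,430,8591
2010-06-01,325,8044
2010-07-01,339,7426
2010-08-01,374,6803
2010-09-01,337,7193
2010-10-01,368,8551
2010-11-01,407,8953
2010-12-01,554,10651
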