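"wavelength_nm","value"
380,0.936964
385,0.946858
390,0.955819
395,0.96387
400,0.971035
405,0.977337
410,0.982805
415,0.987463
420,0.991341
425,0.994465
430,0.996865
435,0.998568
440,0.999604
445,1
450,0.999785
455,0.998986
460,0.997632
465,0.995749
470,0.993363
475,0.990501
480,0.987188
485,0.983448
490,0.979306
495,0.974786
500,0.969908
505,0.964697
510,0.959172
515,0.953354
520,0.947262
525,0.940917
530,0.934335
535,0.927535
540,0.920533
545,0.913345
550,0.905987
555,0.898473
560,0.890818
565,0.883034
570,0.875135
575,0.867133
580,0.85904
585,0.850866
590,0.842622
595,0.834317
600,0.825962
605,0.817566
610,0.809136
615,0.800681
620,0.792208
625,0.783725
630,0.775237
635,0.766753
640,0.758277
645,0.749815
650,0.741372
655,0.732954
660,0.724564
665,0.716208
670,0.707889
675,0.699611
680,0.691378
685,0.683193
690,0.675058
695,0.666977
700,0.658953
705,0.650987
710,0.643081
715,0.635239
720,0.627462
725,0.619751
730,0.612107
735,0.604533
740,0.59703
745,0.589598
750,0.582239
755,0.574953
760,0.567741
765,0.560604
770,0.553543
775,0.546558
780,0.539648
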