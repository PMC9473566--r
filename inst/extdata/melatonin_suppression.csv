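"wavelength_nm","value"
380,0.086911
385,0.115248
390,0.150202
395,0.192396
400,0.242213
405,0.299696
410,0.364456
415,0.435603
420,0.511701
425,0.590778
430,0.670366
435,0.747621
440,0.819468
445,0.882803
450,0.934708
455,0.972679
460,0.99482
465,1
470,0.987954
475,0.9593
480,0.915489
485,0.858684
490,0.791579
495,0.717193
500,0.638645
505,0.558938
510,0.480782
515,0.406457
520,0.337724
525,0.275797
530,0.22136
535,0.174618
540,0.135382
545,0.103161
550,0.077259
555,0.056867
560,0.041139
565,0.029251
570,0.020441
575,0.014039
580,0.009477
585,0.006287
590,0.0041
595,0.002627
600,0.001655
605,0.001024
610,0.000623
615,0.000373
620,0.000219
625,0.000127
630,7.2e-05
635,4e-05
640,2.2e-05
645,1.2e-05
650,6e-06
655,3e-06
660,2e-06
665,1e-06
670,0
675,0
680,0
685,0
690,0
695,0
700,0
705,0
710,0
715,0
720,0
725,0
730,0
735,0
740,0
745,0
750,0
755,0
760,0
765,0
770,0
775,0
780,0
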