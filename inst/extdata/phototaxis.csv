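"wavelength_nm","value"
300,0.249352
305,0.285512
310,0.324652
315,0.366604
320,0.411112
325,0.457833
330,0.506336
335,0.556101
340,0.606531
345,0.656956
350,0.706648
355,0.75484
360,0.800737
365,0.843548
370,0.882497
375,0.916855
380,0.945959
385,0.969233
390,0.986207
395,0.996534
400,1
405,0.996534
410,0.986207
415,0.969233
420,0.945959
425,0.916855
430,0.882497
435,0.843548
440,0.800737
445,0.75484
450,0.706648
455,0.656956
460,0.606531
465,0.556101
470,0.506336
475,0.457833
480,0.411112
485,0.366604
490,0.324652
495,0.285512
500,0.249352
505,0.216265
510,0.18627
515,0.159326
520,0.135335
525,0.114162
530,0.095634
535,0.07956
540,0.065729
545,0.053926
550,0.043937
555,0.03555
560,0.028566
565,0.022794
570,0.018063
575,0.014215
580,0.011109
585,0.008622
590,0.006645
595,0.005086
600,0.003866
605,0.002918
610,0.002187
615,0.001628
620,0.001204
625,0.000884
630,0.000644
635,0.000467
640,0.000335
645,0.00024
650,0.00017
655,0.00012
660,8.4e-05
665,5.8e-05
670,4e-05
675,2.7e-05
680,1.9e-05
685,1.3e-05
690,8e-06
695,6e-06
700,4e-06
705,2e-06
710,2e-06
715,1e-06
720,1e-06
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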