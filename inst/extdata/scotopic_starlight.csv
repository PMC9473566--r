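"wavelength_nm","value"
380,0.007683
385,0.011324
390,0.016423
395,0.023439
400,0.032918
405,0.045491
410,0.061863
415,0.082785
420,0.109014
425,0.14126
430,0.180123
435,0.22601
440,0.279059
445,0.339058
450,0.40538
455,0.476937
460,0.552167
465,0.629055
470,0.705209
475,0.777959
480,0.844511
485,0.90212
490,0.948272
495,0.980871
500,0.998392
505,1
510,0.985619
515,0.955934
520,0.912341
525,0.856833
530,0.791855
535,0.72012
540,0.644427
545,0.567483
550,0.491748
555,0.419316
560,0.351845
565,0.290516
570,0.236048
575,0.188729
580,0.148487
585,0.11496
590,0.087583
595,0.065659
600,0.048438
605,0.035163
610,0.025119
615,0.017657
620,0.012214
625,0.008314
630,0.005568
635,0.00367
640,0.00238
645,0.001519
650,0.000954
655,0.00059
660,0.000359
665,0.000215
670,0.000126
675,7.3e-05
680,4.2e-05
685,2.3e-05
690,1.3e-05
695,7e-06
700,4e-06
705,2e-06
710,1e-06
715,1e-06
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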