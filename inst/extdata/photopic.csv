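"wavelength_nm","value"
380,0.000146
385,0.00024
390,0.000388
395,0.000618
400,0.000972
405,0.001506
410,0.0023
415,0.003463
420,0.00514
425,0.007521
430,0.01085
435,0.015431
440,0.021634
445,0.029901
450,0.040743
455,0.054728
460,0.072473
465,0.094612
470,0.121763
475,0.154485
480,0.193224
485,0.238253
490,0.289614
495,0.347058
500,0.410003
505,0.477502
510,0.548234
515,0.620525
520,0.692397
525,0.761647
530,0.825953
535,0.882996
540,0.930605
545,0.966884
550,0.990343
555,1
560,0.995444
565,0.976869
570,0.945058
575,0.901328
580,0.847443
585,0.785489
590,0.717749
595,0.646559
600,0.574177
605,0.502674
610,0.43384
615,0.369126
620,0.309616
625,0.25602
630,0.208702
635,0.167719
640,0.132875
645,0.103778
650,0.079904
655,0.06065
660,0.045384
665,0.033479
670,0.024347
675,0.017455
680,0.012337
685,0.008596
690,0.005904
695,0.003998
700,0.002669
705,0.001756
710,0.00114
715,0.000729
720,0.00046
725,0.000286
730,0.000175
735,0.000106
740,6.3e-05
745,3.7e-05
750,2.1e-05
755,1.2e-05
760,7e-06
765,4e-06
770,2e-06
775,1e-06
780,1e-06
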