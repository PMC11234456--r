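# Molar extinction coefficient of oxygenated hemoglobin, cm^-1 / (mol/l).
# SYNTHETIC compilation: reconstructed from widely quoted characteristic values
# of the standard public oxyhemoglobin tabulations (Soret peak near 414 nm,
# Q-bands at 542/577 nm, isosbestic points near 500/529/548/570/585 nm, red-region
# minimum near 690 nm); intermediate values are smooth interpolants, not a copy of
# any published table. Intended for forward/inverse modeling consistency, not for
# absolute reference use.
wavelength_nm,epsilon_cm1_M
400,266232
405,350000
410,466840
414,524280
418,508000
420,480360
425,351000
430,246072
435,160000
440,102580
445,78000
450,62816
455,52000
460,44480
465,38000
470,33209
475,29500
480,26629
485,25000
490,23684
495,22000
500,20932
505,20100
510,20201
515,21500
520,24202
525,30500
530,39956
535,47000
540,53236
542,54124
545,53800
548,50000
550,43016
555,36000
560,32613
565,36500
570,44932
574,56000
577,62000
580,53412
583,40000
586,30000
590,14500
595,7300
600,3200
605,2150
610,1506
615,1166
620,942
625,740
630,610
635,510
640,442
645,400
650,368
655,340
660,320
665,305
670,294
675,285
680,278
685,276
690,276
695,280
700,290
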