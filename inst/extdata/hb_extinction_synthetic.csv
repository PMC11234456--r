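# Molar extinction coefficient of deoxygenated (reduced) hemoglobin, cm^-1 / (mol/l).
# SYNTHETIC compilation: reconstructed from widely quoted characteristic values of
# the standard public deoxyhemoglobin tabulations (Soret peak near 432 nm, single
# Q-band at 555 nm, isosbestic points shared with the oxy spectrum, slowly decaying
# red tail); intermediate values are smooth interpolants, not a copy of any
# published table. Intended for forward/inverse modeling consistency, not for
# absolute reference use.
wavelength_nm,epsilon_cm1_M
400,223296
405,290000
410,393308
415,430000
420,407560
425,455000
430,528600
432,533560
435,500000
440,413280
445,259000
450,103292
455,65000
460,40000
465,24000
470,16156
475,14400
480,14550
485,15500
490,16684
495,18500
500,20862
505,23000
510,25773
515,28500
520,31256
525,35000
530,39437
535,43000
540,46592
545,49500
550,51000
555,53412
560,53292
565,50000
570,45072
575,41000
580,37020
585,33800
590,28000
595,21000
600,14677
605,11600
610,9443
615,7700
620,6510
625,5600
630,4930
635,4430
640,4066
645,3780
650,3556
655,3380
660,3227
665,3070
670,2795
675,2590
680,2407
685,2220
690,2051
695,1915
700,1795
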