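# Synthetic compilation of hemoglobin molar extinction anchor points.
# Columns: wavelength_nm, eps_oxy, eps_deoxy.
# Units: decadic (base-10) molar extinction, cm^-1 / (mol/L), for the
# 64500 g/mol hemoglobin tetramer.
# These anchors are a hand-built approximation to the commonly used
# oxy/deoxy-hemoglobin compilations (double oxyhemoglobin peak at 542/577 nm,
# deoxyhemoglobin peak at 555 nm and 760 nm shoulder, near-infrared
# isosbestic point close to 800 nm). They are NOT the original literature
# tables; treat them as a synthetic stand-in of realistic shape and scale.
# Whole-blood absorption (mm^-1) is derived at load time assuming
# hematocrit 0.43, MCHC 345 g/L RBC (=> 148.35 g/L blood, 2.30e-3 mol/L)
# and the natural-log convention: mu_a = ln(10) * eps * C_molar / 10.
# Intermediate wavelengths are filled by monotone (pchip) interpolation of
# log(eps) onto a 1 nm grid.
wavelength_nm	eps_oxy	eps_deoxy
450	62816	103292
455	51000	91000
460	44480	82000
465	38500	71000
470	33209	58000
475	29539	47000
480	26629	37000
485	24500	30000
490	23684	25000
495	22300	22000
500	20932	20862
505	20300	22500
510	20035	25773
515	21000	29000
520	24202	33000
525	30000	36500
530	39000	39037
535	46500	43000
540	53236	46592
545	52000	49500
550	43016	52100
555	36000	53412
560	32613	53788
565	34000	47500
570	44480	44480
574	53000	42000
577	55540	40000
580	50104	37000
585	35000	30000
590	15500	24000
595	7000	18500
600	3200	14677
605	2250	11800
610	1506	9500
620	1100	7100
630	800	5600
640	508	4500
650	368	3750
660	320	3227
670	294	2800
680	276	2407
690	276	2100
700	290	1794
710	314	1600
720	348	1450
730	390	1300
740	446	1250
750	518	1405
760	586	1549
770	650	1400
780	710	1150
790	756	950
800	816	762
810	864	718
820	916	700
835	995	691
850	1058	691
875	1138	720
900	1198	760
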