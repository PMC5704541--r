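gene	ftype	complex	strand	start	end	frame_anchor
ND1	mRNA	I	H	3307	4262	3307
ND2	mRNA	I	H	4470	5511	4470
COX1	mRNA	IV	H	5904	7445	5904
COX2	mRNA	IV	H	7586	8269	7586
ATP8	mRNA	V	H	8366	8572	8366
ATP6	mRNA	V	H	8527	9207	8527
COX3	mRNA	IV	H	9207	9990	9207
ND3	mRNA	I	H	10059	10404	10059
ND4L	mRNA	I	H	10470	10766	10470
ND4	mRNA	I	H	10760	12137	10760
ND5	mRNA	I	H	12337	14148	12337
ND6	mRNA	I	L	14149	14673	14673
CYTB	mRNA	III	H	14747	15887	14747
TRNF	tRNA	none	H	577	647	NA
TRNV	tRNA	none	H	1602	1670	NA
TRNL1	tRNA	none	H	3230	3304	NA
TRNI	tRNA	none	H	4263	4331	NA
TRNQ	tRNA	none	L	4329	4400	NA
TRNM	tRNA	none	H	4402	4469	NA
TRNW	tRNA	none	H	5512	5579	NA
TRNA	tRNA	none	L	5587	5655	NA
TRNN	tRNA	none	L	5657	5729	NA
TRNC	tRNA	none	L	5761	5826	NA
TRNY	tRNA	none	L	5826	5891	NA
TRNS1	tRNA	none	L	7446	7514	NA
TRND	tRNA	none	H	7518	7585	NA
TRNK	tRNA	none	H	8295	8364	NA
TRNG	tRNA	none	H	9991	10058	NA
TRNR	tRNA	none	H	10405	10469	NA
TRNH	tRNA	none	H	12138	12206	NA
TRNS2	tRNA	none	H	12207	12265	NA
TRNL2	tRNA	none	H	12266	12336	NA
TRNE	tRNA	none	L	14674	14742	NA
TRNT	tRNA	none	H	15888	15953	NA
TRNP	tRNA	none	L	15956	16023	NA
RNR1	rRNA	none	H	648	1601	NA
RNR2	rRNA	none	H	1671	3229	NA
CR	noncoding	none	H	16024	16569	NA
CR	noncoding	none	H	1	576	NA
NC01	noncoding	none	H	3305	3306	NA
NC02	noncoding	none	H	4401	4401	NA
NC03	noncoding	none	H	5580	5586	NA
NC04	noncoding	none	H	5656	5656	NA
NC05	noncoding	none	H	5730	5760	NA
NC06	noncoding	none	H	5892	5903	NA
NC07	noncoding	none	H	7515	7517	NA
NC08	noncoding	none	H	8270	8294	NA
NC09	noncoding	none	H	8365	8365	NA
NC10	noncoding	none	H	14743	14746	NA
NC11	noncoding	none	H	15954	15955	NA
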