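subject_id,sex,age,affected_hemisphere,days_T0,days_T1,fmaue_T0,fmaue_T1
1,F,64,L,13,95,8,30
2,M,59,L,15,68,61,65
3,M,78,L,15,109,55,64
9,M,51,L,26,89,4,11
10,M,58,L,22,107,65,66
12,F,76,R,28,112,60,60
13,M,78,L,26,97,63,63
15,M,80,L,19,96,6,16
16,M,77,L,19,107,49,60
17,F,70,R,22,97,62,65
19,M,60,R,33,85,4,4
20,M,72,R,45,82,4,6
24,M,52,R,32,96,4,4
27,M,51,R,21,93,66,66
28,M,81,R,24,66,4,9
29,M,76,L,34,82,66,66
30,M,79,L,31,99,63,66
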