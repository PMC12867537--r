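subject_id,sex,age,affected_hemisphere,days_T0,days_T1,fmaue_T0,fmaue_T1
2,M,53,R,4,105,0,23
3,F,71,L,3,156,66,66
4,M,77,L,3,150,57,62
5,M,58,R,2,86,21,64
6,F,79,L,2,93,66,66
7,F,75,L,3,88,4,43
11,M,73,L,3,250,55,60
12,F,78,L,2,212,0,63
14,M,50,R,4,102,4,12
15,M,50,L,2,303,59,66
16,F,72,R,2,301,64,66
17,M,52,R,2,138,52,60
18,M,64,R,3,175,2,22
20,M,79,L,2,130,66,66
22,M,82,L,1,134,12,59
24,F,53,R,4,96,31,62
25,M,52,R,3,97,6,44
26,M,64,L,3,100,0,19
27,M,64,R,2,88,24,28
30,M,64,L,8,102,32,65
32,M,53,L,3,93,66,66
37,M,60,R,1,108,57,64
38,M,69,L,3,97,8,13
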