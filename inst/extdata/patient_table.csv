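patient,sex,age,duration_y,updrs3_on_med,updrs3_off_med,ledd,subtype,main_symptoms,contact_left,contact_right
1,F,60,10,19,37,1358,AR,Motor fluctuation,C3,C10
2,M,71,11,22.5,38.5,1836,AR,Motor fluctuation; Dyskinesia,C2,C10
3,F,55,14,9,48.5,1524,T,Motor fluctuation; Dyskinesia,C3,C11
4,F,70,6,21,42,900,AR,Motor fluctuation,C1,C10
5,M,56,16,17,44,1214,T,Motor fluctuation,C1,C11
6,F,60,23,24.5,27.5,1248,T,Motor fluctuation,C3,C11
7,M,47,30,16,29,980,AR,Motor fluctuation; Dyskinesia,C3,C10
8,M,65,18,34,38,1400,AR,Motor fluctuation; Dyskinesia,C2,C9
9,M,71,12,15,27,832,T,Motor fluctuation; Dyskinesia,C3,C11
10,F,69,11,28,61,1364,AR,Motor fluctuation,C2,C11
11,M,48,5,47,74,1836,AR,Truncal dystonia,C1,C10
12,M,53,13,20,31,1820,AR,Axial rigidity; Dyskinesia,C3,C10
13,M,65,24,19.5,31.5,1696,AR,Motor fluctuation; FOG,C2,C11
14,F,69,12,23,41,850,AR,Motor fluctuation,C2,C11
15,M,49,15,23,48,1530,T,Dyskinesia,C3,C11
16,F,68,7,34,76,1200,T,Motor fluctuation; Dyskinesia,C1,C9
17,M,70,16,13,29,1150,AR,Motor fluctuation; FOG; VH to DA,C3,C11
18,M,57,9,23,47,799,AR,Motor fluctuation,C2,C9
19,F,54,17,18,34.5,1790,AR,Motor fluctuation; Dyskinesia,C2,C8
20,M,53,24,28,44,710,AR,Biphasic dyskinesia,C0,C10
21,M,68,15,73,78,3502.5,AR,Motor fluctuation; Dyskinesia,C3,C10
22,M,60,17,37,40,940,AR,Axial rigidity; FOG,C1,C9
23,M,56,13,26,55,892,T,Motor fluctuation; Axial rigidity,C3,C11
24,F,71,8,16,30,1100,AR,Motor fluctuation; FOG,C3,C10
25,M,62,14,27,50,948,AR,Motor fluctuation,C3,C10
26,M,58,14,22,67.5,1750,AR,Motor fluctuation,C1,C11
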