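patient,position,probe,nivbs_mm,ref_mm
1,A,1,4.86,4.83
1,A,2,4.67,4.82
1,A,3,4.87,4.81
1,A,4,4.78,4.85
1,P,1,5.12,4.94
1,P,2,4.87,4.97
1,P,3,4.91,4.99
1,P,4,4.88,5.00
1,L,1,3.92,3.79
1,L,2,3.92,3.84
1,L,3,3.73,3.82
1,L,4,3.79,3.77
1,R,1,4.16,3.88
1,R,2,3.89,3.91
1,R,3,3.96,3.93
1,R,4,3.58,3.78
2,A,1,4.13,4.10
2,A,2,3.99,4.06
2,A,3,4.10,3.99
2,A,4,4.07,4.01
2,P,1,4.16,4.10
2,P,2,4.15,4.15
2,P,3,4.21,4.20
2,P,4,4.16,4.15
2,L,1,3.92,3.73
2,L,2,3.75,3.76
2,L,3,3.58,3.78
2,L,4,3.92,3.75
2,R,1,3.89,3.93
2,R,2,3.73,3.81
2,R,3,3.79,3.83
2,R,4,3.96,3.87
3,A,1,3.79,3.72
3,A,2,3.54,3.65
3,A,3,3.61,3.61
3,A,4,3.78,3.68
3,P,1,3.86,3.95
3,P,2,4.02,3.99
3,P,3,3.98,3.94
3,P,4,4.04,3.96
3,L,1,3.26,3.49
3,L,2,3.66,3.54
3,L,3,3.74,3.52
3,L,4,3.59,3.55
3,R,1,3.56,3.58
3,R,2,3.57,3.56
3,R,3,3.40,3.51
3,R,4,3.45,3.50
4,A,1,3.59,3.63
4,A,2,3.52,3.59
4,A,3,3.63,3.61
4,A,4,3.55,3.59
4,P,1,3.77,3.76
4,P,2,3.77,3.81
4,P,3,3.77,3.74
4,P,4,3.79,3.73
4,L,1,3.40,3.51
4,L,2,3.47,3.47
4,L,3,3.51,3.53
4,L,4,3.39,3.49
4,R,1,3.50,3.32
4,R,2,3.15,3.31
4,R,3,3.43,3.38
4,R,4,3.24,3.35
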