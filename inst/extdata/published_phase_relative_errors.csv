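phase,sample,glycyrrhizic_acid,liquiritin,isoliquiritin,total_flavonoids
1,a,1.82,1.72,8.84,0.86
1,b,1.69,3.46,12.25,3.19
1,c,2.28,0.97,1.78,3.17
1,d,3.17,2.41,16.86,0.06
1,e,5.65,3.38,0.58,1.48
1,f,5.22,5.15,3.86,7.75
1,g,6.01,4.76,15.47,3.75
1,h,1.78,3.10,38.09,3.93
1,i,5.54,4.99,NA,NA
1,j,1.51,NA,NA,NA
1,k,2.76,NA,NA,NA
2,a,2.78,3.09,4.76,2.88
2,b,4.29,3.30,29.87,6.78
2,c,0.04,10.11,36.90,9.42
2,d,6.36,8.65,15.08,9.49
2,e,0.81,5.88,5.46,15.34
2,f,4.46,14.83,5.44,11.11
2,g,0.85,1.55,36.67,13.23
2,h,3.36,4.04,0.09,17.39
2,i,0.83,1.24,2.97,14.29
2,j,12.58,19.25,8.48,11.51
2,k,5.31,5.16,4.78,10.28
2,l,4.29,15.46,4.64,2.86
2,m,13.78,5.71,22.78,3.04
2,n,2.30,12.58,18.42,6.68
2,o,NA,NA,1.61,9.11
3,a,51.19,14.08,4.01,9.60
3,b,4.64,11.55,92.73,2.82
3,c,7.92,22.88,78.88,2.76
3,d,1.65,10.59,55.67,21.92
3,e,18.76,7.47,74.38,12.41
3,f,6.53,25.21,99.38,22.22
3,g,NA,5.99,3.78,34.93
3,h,NA,10.84,49.16,10.74
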