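lipid,plot,mean_molepct,se_molepct
11:0,glade_crown,0.72,0.04
11:0,moran_crown,0.93,0.08
11:0,glade_surface,0.72,0.15
11:0,moran_surface,0.46,0.05
12:0,glade_crown,2.90,0.11
12:0,moran_crown,2.08,0.07
12:0,glade_surface,3.43,0.11
12:0,moran_surface,2.17,0.07
14:0,glade_crown,4.35,0.20
14:0,moran_crown,2.16,0.07
14:0,glade_surface,3.49,0.19
14:0,moran_surface,2.90,0.13
15:0,glade_crown,1.21,0.09
15:0,moran_crown,1.04,0.05
15:0,glade_surface,0.97,0.05
15:0,moran_surface,1.07,0.04
15:0anteiso,glade_crown,3.02,0.10
15:0anteiso,moran_crown,2.70,0.10
15:0anteiso,glade_surface,2.55,0.10
15:0anteiso,moran_surface,3.22,0.14
15:0iso,glade_crown,3.13,0.10
15:0iso,moran_crown,2.91,0.09
15:0iso,glade_surface,2.86,0.09
15:0iso,moran_surface,3.90,0.13
15:1w8c,glade_crown,NA,NA
15:1w8c,moran_crown,6.66,0.66
15:1w8c,glade_surface,19.82,0.00
15:1w8c,moran_surface,16.22,1.75
15:1w9c,glade_crown,7.75,0.88
15:1w9c,moran_crown,3.72,0.36
15:1w9c,glade_surface,8.64,0.60
15:1w9c,moran_surface,5.64,0.38
16:0,glade_crown,12.15,0.31
16:0,moran_crown,8.35,0.20
16:0,glade_surface,10.25,0.32
16:0,moran_surface,10.03,0.19
16:02OH,glade_crown,1.47,0.09
16:02OH,moran_crown,2.56,0.45
16:02OH,glade_surface,1.82,0.24
16:02OH,moran_surface,1.74,0.12
16:0iso,glade_crown,1.61,0.06
16:0iso,moran_crown,1.37,0.05
16:0iso,glade_surface,1.45,0.05
16:0iso,moran_surface,1.68,0.06
16:1w5c,glade_crown,1.35,0.07
16:1w5c,moran_crown,1.04,0.04
16:1w5c,glade_surface,1.25,0.06
16:1w5c,moran_surface,1.29,0.04
16:1w7c,glade_crown,5.43,0.35
16:1w7c,moran_crown,4.92,0.31
16:1w7c,glade_surface,4.73,0.21
16:1w7c,moran_surface,5.12,0.23
17:0anteiso,glade_crown,1.65,0.07
17:0anteiso,moran_crown,1.80,0.07
17:0anteiso,glade_surface,1.46,0.06
17:0anteiso,moran_surface,1.79,0.07
cy17:0,glade_crown,2.55,0.17
cy17:0,moran_crown,2.26,0.20
cy17:0,glade_surface,2.45,0.14
cy17:0,moran_surface,2.59,0.13
17:0iso,glade_crown,0.79,0.05
17:0iso,moran_crown,0.53,0.03
17:0iso,glade_surface,0.76,0.05
17:0iso,moran_surface,0.72,0.03
17:1w8,glade_crown,1.28,0.17
17:1w8,moran_crown,1.29,0.09
17:1w8,glade_surface,1.68,0.13
17:1w8,moran_surface,1.21,0.08
17:1w7c,glade_crown,3.41,0.34
17:1w7c,moran_crown,9.57,0.89
17:1w7c,glade_surface,6.90,0.86
17:1w7c,moran_surface,7.16,0.67
18:0,glade_crown,4.11,0.16
18:0,moran_crown,3.00,0.14
18:0,glade_surface,3.13,0.15
18:0,moran_surface,2.47,0.07
18:02OH,glade_crown,3.30,0.43
18:02OH,moran_crown,4.18,0.31
18:02OH,glade_surface,3.20,0.17
18:02OH,moran_surface,3.54,0.19
18:1w9c,glade_crown,16.10,0.88
18:1w9c,moran_crown,9.08,0.50
18:1w9c,glade_surface,12.89,0.67
18:1w9c,moran_surface,11.45,0.56
18:2w6c,glade_crown,4.08,0.13
18:2w6c,moran_crown,2.49,0.11
18:2w6c,glade_surface,3.34,0.17
18:2w6c,moran_surface,3.50,0.17
18:3w6c,glade_crown,2.71,0.13
18:3w6c,moran_crown,1.59,0.09
18:3w6c,glade_surface,2.14,0.08
18:3w6c,moran_surface,2.01,0.07
19:0,glade_crown,0.25,0.02
19:0,moran_crown,1.82,0.17
19:0,glade_surface,0.17,0.02
19:0,moran_surface,0.27,0.03
cy19:0,glade_crown,0.47,0.03
cy19:0,moran_crown,0.40,0.04
cy19:0,glade_surface,0.09,0.03
cy19:0,moran_surface,0.49,0.04
19:1w8t,glade_crown,7.57,0.54
19:1w8t,moran_crown,9.08,0.55
19:1w8t,glade_surface,9.84,0.80
19:1w8t,moran_surface,9.48,0.52
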