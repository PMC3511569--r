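variable,plot,trend_mean,trend_q05,trend_q95,range_mean,range_q05,range_q95,sill_mean,sill_q05,sill_q95,nugget_mean,nugget_q05,nugget_q95,nugget_ratio_mean,nugget_ratio_q05,nugget_ratio_q95,cv_r2
abundance_nmol,glade_crown,204.3,99.8,272.9,4.5,0.0,132.9,10864,7098,20234,7672.2,3137.4,15153.3,0.79,0.24,0.99,0.94
abundance_nmol,moran_crown,373.3,314.8,423.4,1.5,0.0,100.5,29362,20854,50591,19549.9,6444.1,39124.7,0.73,0.16,0.98,0.98
abundance_nmol,glade_surface,363.5,156.6,574.3,3.0,0.0,142.2,39545,24616,71824,27732.2,10019.0,53868.1,0.80,0.23,0.99,0.93
abundance_nmol,moran_surface,313.5,145.8,495.4,78.9,7.8,145.2,20413,13262,35273,16429.6,10235.0,22418.8,0.83,0.45,0.99,0.56
fb_ratio,glade_crown,0.9,0.7,1.2,10.5,1.8,27.6,0.14,0.10,0.22,0.10,0.05,0.15,0.78,0.28,0.99,0.89
fb_ratio,moran_crown,0.4,0.4,0.5,3.6,0.3,9.6,0.03,0.02,0.05,0.02,0.01,0.03,0.72,0.17,0.98,0.97
fb_ratio,glade_surface,0.8,0.7,0.9,1.5,0.0,6.0,0.14,0.10,0.22,0.09,0.03,0.14,0.72,0.16,0.98,0.98
fb_ratio,moran_surface,0.5,0.5,0.6,5.1,1.2,21.6,0.03,0.02,0.05,0.02,0.01,0.03,0.75,0.19,0.98,0.94
net_n_min,glade_crown,17.1,-3.7,36.1,13.8,6.9,27.0,1101,750,1869,686.2,286.1,1018.0,0.65,0.18,0.97,0.87
net_n_min,moran_crown,4.5,-4.5,13.5,2.4,0.0,13.8,792,562,1254,540.6,190.8,832.7,0.74,0.17,0.98,0.97
net_n_min,glade_surface,17.1,10.7,23.8,1.5,0.0,10.5,558,402,866,379.8,129.1,573.7,0.73,0.16,0.98,0.98
net_n_min,moran_surface,22.1,16.8,27.2,1.8,0.0,6.0,358,257,561,240.4,80.6,354.4,0.72,0.16,0.98,0.98
veg_cover_pct,glade_crown,29.5,17.5,13.3,9.9,4.2,26.1,413,290,669,282.38,117.16,419.5,0.73,0.21,0.98,0.89
veg_cover_pct,moran_crown,23.6,19.3,28.0,1.5,0.0,4.8,285,206,443,190.96,62.18,277.32,0.72,0.15,0.98,0.98
veg_cover_pct,glade_surface,30.2,25.9,34.3,1.8,0.0,9.9,226,163.0,351,153.97,53.27,232.56,0.74,0.17,0.98,0.98
veg_cover_pct,moran_surface,24.4,17.5,30.2,4.2,0.3,23.1,273,196,422,195.02,80.41,299.53,0.77,0.22,0.99,0.95
nonveg_cover_pct,glade_crown,70.4,60.5,82.1,9.9,4.2,26.1,413,290,669,282.4,117.1,419.5,0.73,0.21,0.98,0.89
nonveg_cover_pct,moran_crown,76.3,71.9,80.6,1.5,0.0,4.8,285,206,443,191.0,62.2,277.3,0.72,0.15,0.98,0.98
nonveg_cover_pct,glade_surface,69.8,65.6,74.0,1.8,0.0,9.9,226,163,351,154.0,53.3,232.6,0.74,0.17,0.98,0.98
nonveg_cover_pct,moran_surface,75.5,69.5,82.2,4.2,0.3,23.1,273,196,422,195.0,80.4,299.5,0.77,0.22,0.99,0.95
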