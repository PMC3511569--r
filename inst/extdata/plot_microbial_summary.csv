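metric,plot,mean,se
abundance_nmol,glade_crown,205.25,15.65
abundance_nmol,moran_crown,374.19,25.03
abundance_nmol,glade_surface,363.90,28.00
abundance_nmol,moran_surface,301.73,17.80
fb_ratio,glade_crown,0.93,0.06
fb_ratio,moran_crown,0.43,0.03
fb_ratio,glade_surface,0.83,0.06
fb_ratio,moran_surface,0.55,0.03
gm_pos,glade_crown,0.010,0.001
gm_pos,moran_crown,0.016,0.001
gm_pos,glade_surface,0.014,0.001
gm_pos,moran_surface,0.015,0.001
gm_neg,glade_crown,0.020,0.002
gm_neg,moran_crown,0.048,0.005
gm_neg,glade_surface,0.049,0.005
gm_neg,moran_surface,0.040,0.004
stress_ratio,glade_crown,1.04,0.03
stress_ratio,moran_crown,1.12,0.03
stress_ratio,glade_surface,NA,NA
stress_ratio,moran_surface,1.28,0.03
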