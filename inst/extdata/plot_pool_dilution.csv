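plot,quantity,mean,se
glade_crown,gross_nitrification,0.06,0.02
moran_crown,gross_nitrification,0.38,0.09
glade_crown,nh4_consumption,0.44,0.07
moran_crown,nh4_consumption,0.83,0.14
glade_crown,no3_consumption,0.09,0.02
moran_crown,no3_consumption,0.61,0.10
glade_crown,net_nh4,-0.24,0.04
moran_crown,net_nh4,-0.47,0.11
glade_crown,net_no3,-0.03,0.01
moran_crown,net_no3,-0.24,0.13
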