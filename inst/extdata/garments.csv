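name,category,i_clu_clo
bra_and_panties,top,0.05
t_shirt,top,0.08
short_sleeve_shirt,top,0.19
long_sleeve_shirt,top,0.25
sweater,top,0.28
thick_sweater,top,0.35
suit_jacket,top,0.44
winter_jacket,top,0.55
shorts,bottom,0.08
light_trousers,bottom,0.15
trousers,bottom,0.24
thick_trousers,bottom,0.28
skirt,bottom,0.14
ankle_socks,socks,0.02
calf_socks,socks,0.03
thick_socks,socks,0.06
sandals,shoes,0.02
shoes,shoes,0.03
boots,shoes,0.10
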