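specimen,morphotype,mechanical_advantage_tip,out_lever_tip_mm,preserved_length_mm
M1409,robust,0.089,401,185
M1399,gracile,0.191,335,335
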