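# Gracile morphotype preset (specimen analogue: BRLSI M1399).
#
# A complete 335 mm longirostrine skull with a slenderer, shallower
# rostrum, a relatively tall cranium and a larger orbit than the robust
# morphotype. The rostrum-base-height / cranium-height ratio (28/72 = 0.39)
# is deliberately smaller than the robust preset's (40/75 = 0.53),
# encoding the printed proportional contrast between the two skulls.
# See robust.yaml for field-by-field documentation.
label: gracile
total_skull_length: 335
rostrum_fraction: 0.60
rostrum_base_height: 28
rostrum_base_width: 22
taper_exponent: 0.85
cranium_height: 72
cranium_width: 62
orbit_diameter: 46
target_edge_length: 4
tip_fraction: 0.25
tooth_row_start_fraction: 0.42
preserved_fraction: 1.0
random_seed: 12
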