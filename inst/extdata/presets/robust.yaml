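# Robust morphotype preset (specimen analogue: BRLSI M1409).
#
# A large-juvenile longirostrine skull with a proportionally long, deep
# rostrum, robust cranium and modest orbit. The anterior rostrum of the
# fossil is broken away: the estimated complete skull length is 401 mm, of
# which 185 mm (preserved_fraction = 0.4613) is represented, so the
# pipeline truncates the generated mesh before analysis. Its foremost
# preserved bite position is therefore analogous to the mid-tooth-row bite
# of the gracile morphotype.
#
# Fields (all lengths mm):
#   label                     identifier used in node-set and case labels
#   total_skull_length        estimated complete skull length
#   rostrum_fraction          share of length anterior to the orbit region
#   rostrum_base_height       rostrum cross-section height at its base
#   rostrum_base_width        rostrum cross-section width at its base
#   taper_exponent            snout taper shape (1 = linear)
#   cranium_height            posterior cranium height
#   cranium_width             posterior cranium width
#   orbit_diameter            diameter of the lateral orbital void
#   target_edge_length        requested mesh edge length
#   tip_fraction              blunt-tip size as a fraction of base section
#   tooth_row_start_fraction  tooth row start, fraction of total length
#                             from the posterior end
#   preserved_fraction        represented fraction of total length
#   random_seed               seed for node-set subsampling
label: robust
total_skull_length: 401
rostrum_fraction: 0.65
rostrum_base_height: 40
rostrum_base_width: 30
taper_exponent: 1.0
cranium_height: 75
cranium_width: 64
orbit_diameter: 38
target_edge_length: 4
tip_fraction: 0.25
tooth_row_start_fraction: 0.38
preserved_fraction: 0.4613
random_seed: 11
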