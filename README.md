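# craniofea

Comparative cranial finite-element feeding biomechanics for longirostrine
marine-reptile skulls.

Coexisting Early Jurassic ichthyosaurs with superficially similar,
dolphin-like skulls may have divided their prey by biting differently: a
robust-snouted morphotype suited to slow, forceful, sustained bites on
hard prey, and a gracile-snouted morphotype suited to fast, weak snaps at
soft prey. Testing that idea biomechanically combines three classical
tools, which this package implements as one reproducible, fully tested
pipeline for comparative biomechanists:

1. **Dry-skull muscle force estimation.** For each of the seven jaw
   muscles (mAMEpr, mAMEsu, mAMEme, mAMIps, mAMIpt, mAMP, mDM), the
   maximum force from reconstructed dimensions:

   *F*<sub>max</sub> = (*V* / (*L*/3)) · *P*

   with muscle volume *V* (mm³), length *L* (mm), fibre length *L*/3,
   and specific muscle stress *P* = 300 kPa.

2. **Finite-element analysis.** Linear-elastic tet4 models of the two
   crania (homogeneous bone, E = 15,000 MPa, ν = 0.29), loaded
   bilaterally by the muscle forces via the two-nodes method and
   constrained at the basicranium and at 20-node bite sets
   (posterior / mid / anterior tooth row), yielding per-element von Mises
   stress fields and volume-weighted regional summaries.

3. **Jaw lever mechanics.** Mechanical advantage *A* = in-lever /
   out-lever, and bite force *F* = *F*<sub>max</sub> · *A* along the
   tooth row.

Because the CT-derived skull reconstructions are not required, skull
geometry is generated parametrically: tapered elliptical rostrum fused to
a box-like cranium with orbital voids, with all muscle-attachment,
constraint and bite-point node sets derived deterministically. Two
shipped presets encode the published proportional contrasts (robust:
401 mm estimated length, 46% preserved; gracile: 335 mm, complete,
slenderer rostrum, larger orbit).

## Worked example

```r
library(craniofea)

# Muscle forces for the gracile specimen (dimensions from the packaged
# fixture table; integers round half away from zero, as in report tables)
muscle_force_table("M1399")[, c("muscle", "length_mm", "volume_mm3",
                                "cross_section_rounded", "force_rounded")]
#>   muscle length_mm volume_mm3 cross_section_rounded force_rounded
#> 1 mAMEpr        83       1556                    56            17
#> 2 mAMEsu        62       2515                   122            37
#> 3 mAMEme        77       2094                    82            24
#> 4 mAMIps        85       2660                    94            28
#> 5 mAMIpt        37       1591                   129            39
#> 6   mAMP        54       1950                   108            33
#> 7    mDM        57       7214                   380           114

f_total <- total_muscle_force(specimen_muscles("M1399"))
f_total
#> [1] 291.1256                      # prints as 291 N in report tables

# Tip-of-tooth-row bite force from the lever model (A = 0.191)
round_half_out(bite_force(f_total, 0.191))
#> [1] 56                            # N

# Parametric gracile skull at default granularity
mesh <- build_skull_mesh(morphotype_preset("gracile"))
mesh
#> Skull mesh 'gracile': 4648 nodes, 20148 tetrahedra
#>   extent x: [0, 335] mm; volume 492735 mm^3
#>   regions: nasal=3042, orbital=1116, palate=1550, posterior_cranium=4798, rostrum=9642
#>   node sets: 27
```

The numbers mean: the gracile specimen's seven muscles produce 291 N in
total, which its relatively high mechanical advantage converts into a
56 N bite at the snout tip; the robust specimen (158 N total, A = 0.089)
manages only 14 N there. The FE stage then shows where those muscle loads
stress each skull:

```r
res <- run_pipeline(list(output_dir = "out"))   # full default run, ~10 s
res$contrast
#> Stress contrast (gracile vs robust)
#>   nasal shift index (posterior -> mid): gracile = 17.5, robust = 1.4
#>   rostrum+nasal mean ratio (gracile/robust): bite_mid = 2.6, bite_posterior = 0.401
#>   gracile_rostrum_stress_higher: TRUE
#>   gracile_shift_greater: TRUE
#>   gracile_nasal_max_at_mid: TRUE
```

i.e. the gracile rostrum carries higher stress than the robust one under
matched biting, its stresses shift far more when the bite point moves,
and its nasal region is most stressed at the mid-tooth-row bite — the
stress-based argument for dietary niche partitioning, reproduced
directionally on synthetic geometry. `run_pipeline()` also writes the
meshes and stress fields (legacy ASCII VTK, 0–3 MPa contour convention),
all tables as CSV, and a markdown report with provenance (config hash,
seed, mesh statistics). A thin CLI wrapper lives at
`inst/scripts/craniofea.R`.

See the methods vignette (`vignettes/craniofea-methods.Rmd`) for the
model assumptions, parameter choices, numerical decisions and known
limitations.

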