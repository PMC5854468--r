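# curvtrack

Bacterial actin (MreB) filaments move around the circumference of
rod-shaped cells, steering cell-wall synthesis into the hoop-like pattern
that builds and maintains rod shape. `curvtrack` is an R package for the
two computations behind that observation:

1. **Orientation energetics.** An intrinsically curved, membrane-bound
   elastic filament on a surface with principal curvatures
   (&kappa;&#8321;, &kappa;&#8322;) feels a normal curvature
   &kappa;&#8345;(&theta;) = &kappa;&#8321;cos&sup2;&theta; +
   &kappa;&#8322;sin&sup2;&theta; along its binding direction &theta;
   (Euler's relation). The package evaluates the total energy

   *E*(&theta;, a) = (B/2) L (&kappa;<sub>adopt</sub> + &kappa;&#8320;)&sup2;
   &minus; &epsilon;<sub>bind</sub> L/&delta;
   + *E*<sub>Helfrich</sub>(a) + *P* &middot; &Delta;V(a)

   with beam rigidity B = E&middot;I, preferred curvature &kappa;&#8320;
   (radius ~100 nm), full-length adhesion, Helfrich bending/tension of a
   membrane groove of depth *a*, and pressure&ndash;volume work against
   turgor. Minimizing over *a* at each angle yields the landscape
   &Delta;E(&theta;) = E(&theta;) &minus; E(90&deg;), its minimum
   (circumferential on rods), and the well depth versus thermal energy.

2. **Trajectory and contour statistics.** Orthogonal (total least squares)
   line fits of tracks; MSD motion classification via
   MSD(t) = 4Dt + (Vt)&sup2; (plus localization-noise and power-law
   variants) and the log&ndash;log slope &alpha;; the standard directional
   filters (R&sup2; > 0.9, displacement > 0.2 &mu;m, velocity >
   10&#8315;&#8313; &mu;m/s, log&ndash;log R&sup2; > 0.6); track angles to
   the cell midline with the fold to [0&deg;, 90&deg;] and
   &sigma;&#8329;&#8320; = &radic;(&Sigma;(x&#7522; &minus; 90)&sup2;/N);
   pairwise angle differences and dot products DP = cos(&theta;&#7522;
   &minus; &theta;&#11388;) binned by distance; 3-point contour curvature,
   pill-mesh width/midline extraction, principal-curvature ratios
   (&kappa;&#8322; = 1/r<sub>cell</sub>), tangent correlation G(l), and
   log-area doubling times.

A synthetic-data module generates rod/sphere/bulged-sphere contours,
circumferential and isotropic track populations, ballistic/diffusive MSD
fixtures, and the random-angle null field (1 &mu;m displacement, 25 nm/s,
recorded R&sup2; = 0.95 on a 100 &times; 100 &mu;m area), so the full
pipeline runs and is tested without any microscopy data.

## Worked example

```r
library(curvtrack)

## 1. Orientation energy landscape with default mechanics
energy_profile(mechanics_params())
#> Filament binding-angle energy profile
#>   surface: kappa1 = 0, kappa2 = -2.22222 (1/um)
#>   argmin theta   90 deg
#>   well depth     73.2 kT (dE at 0 deg vs 90 deg)
#>   > 1 kT well    TRUE
```

With defaults (10 kT/monomer adhesion, 2 GPa modulus, 0.45 &mu;m cell
radius, turgid regime) the energy minimum is at &theta; = 90&deg; — the
filament binds circumferentially — and misorienting it by 90&deg; costs
~73 kT, far beyond thermal fluctuations.

```r
## 2. Synthetic circumferential tracks in a rod, analyzed end to end
rod <- generate_contour(contour_scenario("rod", width = 1, length = 4))
ts  <- generate_tracks(trajectory_scenario("circumferential", n_tracks = 150,
                                           angular_noise = 4, seed = 1), rod)
rep <- apply_filters(summarize_tracks(ts))
rep
#> Track filter: 150 of 150 tracks retained
ang <- angle_to_midline(rep$retained$line_angle, rep$retained$mean_x,
                        rep$retained$mean_y, rod)
sigma90(ang)
#> [1] 30.5
pairwise_statistics(rep$retained)
#> Pairwise track statistics: 150 eligible tracks, 11175 pairs
#>   median delta-theta (d <= 1 um): 28.20 deg
#>   mean DP (d <= 1 um): 0.752
```

The simulated population is circumferential but noisy
(&sigma;&#8329;&#8320; &asymp; 30&deg;, close-pair median angle difference
&asymp; 28&deg;). The corresponding null:

```r
## 3. Random-angle null model
random_angle_null(500, seed = 1)
#> [1] 44.99
```

Randomly oriented trajectories give a median pairwise angle difference of
45&deg;; aligned motion shows up as values well below it.

A thin command-line wrapper is installed at `inst/exec/curvtrack`
(subcommands `simulate`, `analyze-tracks`, `analyze-contours`,
`energy-profile`, `sweep`, `null-sim`).

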