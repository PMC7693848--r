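# spiralfoil

Desk-scale modelling of a spiral inertial-microfluidic device that
enriches circulating tumor cells (CTCs) from blood by size, using a
cambered hydrofoil and a half-elliptic separation wall placed downstream
of the spiral. The package is aimed at microfluidic-device designers and
computational scientists who want to study this class of separator — its
flow topology, particle routing and enrichment statistics — without a
commercial CFD license or wet-lab data.

In a spiral channel of rectangular cross-section, the competition between
the net inertial lift

    F_L = 2 rho U_avg^2 a^4 c_L / D_H^2

and the Dean-flow drag

    F_D = 3 pi mu U_D a

focuses particles of diameter `a` onto size-dependent lateral axes
(`F_L/F_D ∝ a^3`). A NACA9730 hydrofoil at a 30° attack angle then widens
the gap between the 17 µm (CTC-like) and 10 µm (WBC-like) streams before
a 50 µm separation wall divides the channel into a 75 µm CTC outlet and a
175 µm waste outlet. Separation quality is scored by the
chromatography-style resolution

    R = 1.18 s_p / (w_CTC + w_WBC)

on the half-height widths of the stream distributions.

The package provides, as testable modules:

* **geometry** — parametric NACA 4-digit sections, hydrofoil placement,
  the half-elliptic wall and the assembled 2D downstream domain;
* **flow** — a depth-averaged incompressible Navier–Stokes solver
  (projection method, immersed solids, calibrated outlet-network
  boundary condition) with point-queryable velocity fields;
* **transport** — finite-size passive-tracer advection with wall
  standoff, outlet classification and downstream stream distributions;
* **distributions** — two-Gaussian intensity-profile fits,
  discretization into seeding weights and the resolution statistic;
* **inertial model** — the lift/Dean force laws, dimensionless numbers
  and the two-stage design rules;
* **performance stats** — recovery, purity, two-cycle WBC depletion,
  viability loss, through-origin linear-fit spiking recovery, enrichment
  factor and volume/time bookkeeping;
* **synthetic data** — seeded generators for every input the pipeline
  consumes.

## Worked example

The closed-form layer is immediate:

```r
library(spiralfoil)

resolution(stream_distribution(100, fwhm = 15.8),
           stream_distribution(160, fwhm = 15.8))
#> Separation resolution R = 2.241 (s_p = 60.00 um, w1+w2 = 31.60 um)

dimensionless_numbers(fluid_props(), 1.2, 300, 100)$re
#> [1] 100

str(cycle_bookkeeping(9.0, c(2, 3), 1.2))
#> List of 3
#>  $ ctc_volume_ml   : num 3.6
#>  $ waste_volume_ml : num 5.4
#>  $ process_time_min: num 7.5
```

The full simulation study — reference and hydrofoil configurations at a
4 µm grid — takes a few minutes on one core:

```r
study <- run_separation_study(config = flow_config(resolution = 4))
study
#> Hydrofoil separation study
#>   outlet back-pressure: -222.0 Pa (reference split 29.7%)
#> -- reference (no hydrofoil) --
#> Separation outcome
#>   CTC-17um   ctc  50.0%  waste  50.0%  stuck  0.0%
#>   WBC-10um   ctc   0.0%  waste 100.0%  stuck  0.0%
#>   R upstream   = 2.24
#>   R downstream = 2.28 (station x = 650 um)
#>   CTC flow split = 29.7%
#> -- with hydrofoil --
#> Separation outcome
#>   CTC-17um   ctc  95.8%  waste   4.2%  stuck  0.0%
#>   WBC-10um   ctc   0.0%  waste 100.0%  stuck  0.0%
#>   R upstream   = 2.24
#>   R downstream = 17.46 (station x = 650 um)
#>   CTC flow split = 36.6%
```

Reading the output: without the hydrofoil the separation wall dissects
the 17 µm stream at its focal peak, so half of those cells are lost to
the waste channel while all 10 µm cells leave through it. With the
hydrofoil, the under-foil jet deflects the 17 µm stream toward the
reference wall and raises the CTC-side flow share from 29.7% to 36.6%;
95.8% of the 17 µm weight now exits the CTC channel with no 10 µm
contamination, and the downstream resolution rises from 2.24 to 17.5 —
past the ≥ 10 design rule for this class of device.

Enrichment statistics work directly on count tables (here synthetic,
seeded):

```r
cc  <- gen_cycle_counts(synth_config(seed = 7), wbc_inlet = 1e6)
wbc_depletion(cc, 2)         # cumulative two-cycle WBC depletion
#> [1] 88.2549
s   <- gen_spiking_series(synth_config(seed = 7))
linear_fit_recovery(s)$rate  # percent recovery from the spiking series
#> [1] 75.99136
```

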