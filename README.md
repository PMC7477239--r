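# onhmorph

Optic nerve head (ONH) morphometry from segmented OCT surfaces, and the
longitudinal statistics of a two-group primate microbead ocular-hypertension
(OHT) study — with a synthetic phantom and cohort generator so that every
stage is testable without imaging data.

## Who this is for

Glaucoma researchers working with segmented spectral-domain OCT volumes of
the ONH (ILM and anterior lamina cribrosa height grids plus a delineated
Bruch's membrane opening ring), and anyone analysing longitudinal
intraocular-pressure (IOP) / structure data from experimental
ocular-hypertension models.

## What it computes

**Morphometry** (per segmented volume, micrometres / mm²):

- **BMO reference plane** — orthogonal least-squares plane through the BMO
  ring: centroid `c`, unit normal `n` (oriented posteriorly) minimising
  Σᵢ ‖(pᵢ − c)·n‖².
- **BMO area** — shoelace area of the ring projected into the plane.
- **Mean LCD** (lamina cribrosa depth) — mean signed perpendicular distance
  `(x − c)·n` of delineated anterior-LC grid nodes whose projection falls
  inside the BMO polygon (positive = posterior).
- **Mean MRW** (BMO minimum rim width) — per BMO point, the minimum
  Euclidean distance to the triangulated ILM, restricted to the neuroretinal
  rim (triangles whose centroid projects inside the BMO polygon); exact
  point-to-triangle closest-point computation.
- **LC visibility** — percentage of the enface BMO area with delineated LC.

**Longitudinal analysis** (per cohort table):

- weekly → monthly IOP aggregation (mean and maximum per 4-week block);
- per-interval structural change statistics (mean, SD, paired t-test);
- group summaries (mean ± SD across animals);
- Pearson partial correlation of IOP with MRW/LCD **controlling for primate**
  (within-subject centring), tested with Fisher's z:
  `z = atanh(ρ̂)·√(n − (k−1) − 3)` for `k` subjects.

**Synthetic data**: `make_phantom_volume()` builds segmented volumes with
analytically known truth (elliptical, possibly tilted BMO; rim-and-cup ILM;
flat/tilted/bowl LC; contiguous missing-LC wedge), and `generate_cohort()`
simulates the study design: 10 animals with unilateral OHT (contralateral
controls) plus 6 with bilateral OHT, microbead injections scheduled by a
re-injection threshold, a saturating dose–response IOP model, and MRW/LCD
trajectories coupled to the monthly IOP rise.

## Worked example

```r
library(onhmorph)

# a phantom eye with a bowl-shaped lamina and 90% LC visibility
ph <- make_phantom_volume(phantom_params(lc_shape = "bowl", seed = 7))
ph$truth
#> Phantom truth: MRW 280.01 um, LCD 230.01 um, BMO area 2.6264 mm^2, LC visibility 90.0%
measure_volume(ph$volume)
#> ONH morphometry
#>   mean MRW:        279.97 um (over 64 BMO points)
#>   mean LCD:        230.01 um (over 3318 LC nodes)
#>   BMO area:        2.6222 mm^2
#>   LC visibility:    90.56 %
```

All four measures recover the constructed truth to well under 1% (the BMO
area is an inscribed 64-gon, hence the 0.16% deficit).

```r
# a full simulated study, and the study's own analyses
tab <- generate_cohort(cohort_params(seed = 42))
monthly_change(tab, "mrw", arm = "oht_right")[2, ]
#>   from_month to_month mean_change sd_change  p_value  n degenerate
#> 2          1        2      -74.59      34.4 3.10e-07 16      FALSE

post <- cohort_arm(tab[tab$month >= 1, ], "oht_right")
partial_correlation(post$mean_iop, post$mrw, post$primate_id)
#> Partial correlation (subject-controlled): rho = -0.747 (n = 112, 16 subjects, df = 95), z = -9.366, p = 7.56e-21
```

The largest rim thinning falls in the month 1→2 interval (where the IOP rise
concentrates) and monthly mean IOP is strongly negatively associated with
MRW once primate effects are removed — the qualitative signature of the
study the simulator emulates.

The packaged per-animal tables reproduce the study's group statistics:

```r
t2 <- load_fixture("table2_morphometry")
gs <- group_summary(t2, "mrw", group = 1, eye = "OD", timepoint = "month7")
sprintf("Group 1 OHT eyes, month-7 MRW: %.1f +/- %.1f um (n = %d)", gs$mean, gs$sd, gs$n)
#> "Group 1 OHT eyes, month-7 MRW: 167.1 +/- 74.9 um (n = 10)"
```

## Command line

```sh
Rscript inst/cli/onh.R simulate-cohort --seed 42 --out cohort.csv
Rscript inst/cli/onh.R monthly-change --cohort cohort.csv --metric mrw --arm oht_right
Rscript inst/cli/onh.R correlate --cohort cohort.csv --x mean_iop --y mrw
Rscript inst/cli/onh.R run --seed 42 --out run1   # full pipeline + manifest
```

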