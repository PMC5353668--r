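# forestdebt

Detection and mapping of **extinction debts** — species committed to
extinction by past habitat loss but not yet gone — for forest-dwelling
terrestrial vertebrates on global latitude/longitude grids.

The package is aimed at macroecologists and conservation scientists working
with gridded range atlases (presence/absence per cell) and two-epoch forest
cover (a pre-industrial baseline and a modern epoch). It answers four
questions: *is there evidence of a debt* (richness tracking past rather
than present forest), *which forest variables matter*, *how large is the
debt per cell*, and *where are the high-debt cells that current
conservation priorities miss*.

## The model

Evidence for a debt is a correlation asymmetry: present richness $S$
correlating more strongly with past forest predictors than with current
ones. Per epoch $t \in \{1500s, 2000s\}$ the package computes four
predictors per cell $i$ — forest area $A_t(i)$, incidence-function
connectivity $\sum_{j\ne i} e^{-\alpha d_{ij}}A_t(j)$, proximity
$\sum_{j\ne i} A_t(j)/d_{ij}^2$, and von Neumann concentration
$\sum_{j\in S(i)} A_t(j)$ — and tests each against richness with a
spatially adjusted correlation (Clifford–Richardson–Hémon effective
degrees of freedom), a semi-partial and a partial correlation (controlling
the other seven predictors), Bonferroni correction, and a permutation
null. Relative importance is decomposed with `lmg`, `first`, `last` and
`genizi` under a case-resampling bootstrap.

Debt magnitude comes from the power species–area relationship
$S = cA^z$: holding $z$ fixed across epochs,

$$S_{eq}(i) = S_{obs}(i)\left(\frac{A_{2000}(i)}{A_{1500}(i)}\right)^{z},
\qquad \mathrm{Debt}(i) = S_{obs}(i) - S_{eq}(i),$$

with $z \in \{0.25, 0.1, 0.15\}$ and a fitted $z$ (log–log OLS slope).
Extinction-risk maps sum IUCN category probabilities (DD 0.0001, LC 0.001,
NT 0.01, VU 0.1, EN 0.667, CR 0.999) over species per cell; top-decile
hotspots of debt, richness and risk are intersected to report
conservation gaps (high-debt cells outside both conventional priority
maps).

Real IUCN/land-use downloads are out of scope; a seeded synthetic-world
generator (`generate_world()`) emulates their statistical structure —
autocorrelated forest fields, pressure-concentrated deforestation,
SAR-generated richness with known $(c, z)$, multinomial IUCN categories —
so the whole pipeline is testable against known ground truth. See the
methods vignette (`vignettes/extinction-debt-methods.Rmd`) for the full
account.

## Worked example

```r
library(forestdebt)

cfg <- analysis_config(
  synthetic = synthetic_config(seed = 42, resolution = 6,
                               taxa = c("reptile", "mammal", "amphibian")),
  B_perm = 199, B_boot = 500)
rep <- run_analysis(cfg)
rep
#> analysis report: 3 taxa, 1200 land cells, seed 42
#>   correlations: 72 rows; SAR fitted z: amphibian=0.233, mammal=0.227, reptile=0.222

rep$sar$mammal
#> SAR fit: S = 2.565 * A^0.2267 (R^2 = 0.442, 1200 cells)

subset(rep$correlations, taxon == "mammal" & predictor %in%
         c("Areas1500", "Areas2000"))[, c("predictor", "method", "r", "p_bonferroni")]
#>  predictor      method        r p_bonferroni
#>  Areas1500     spatial  0.63264     1.48e-08
#>  Areas1500 semipartial -0.01298     1.00e+00
#>  Areas1500     partial -0.01693     1.00e+00
#>  Areas2000     spatial  0.52962     8.13e-06
#>  Areas2000 semipartial  0.00992     1.00e+00
#>  Areas2000     partial  0.01295     1.00e+00

rep$overlap$mammal
#> hotspot overlap report
#>   Jaccard debt~richness 0.177, debt~risk 0.043, richness~risk 0.128
#>   debt hotspot coverage 0.367 (gap fraction 0.633, 76 gap cells)
```

Reading the output: this world was generated with $z_{true} = 0.25$ and
noisy richness; the fitted exponents land near 0.23. The spatial
correlation with *past* forest area (0.63) exceeds the one with *current*
area (0.53) — the debt signature the generator planted. The semi-partial
and partial coefficients collapse toward zero because the eight predictors
are highly collinear, so little unique signal remains once the other seven
are controlled. Two thirds of the top-decile debt cells fall outside both
the richness and risk hotspots — the conservation gap.

`write_report(rep, "out/")` writes tidy CSV tables, per-taxon layer CSVs,
a JSON summary and an md5 manifest.

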