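# neutralsad

Neutral-theory fitting and exact neutrality testing for species abundance
distributions (SADs), built for microbiome OTU tables.

## The scientific problem

Microbial community surveys routinely show that diseased and healthy hosts
carry *compositionally* different communities. A harder question is whether
disease changes the *mechanism* of community assembly: are local communities
put together by deterministic niche forces (competition, habitat filtering),
or are they consistent with Hubbell's neutral theory, in which all
individuals are demographically equivalent and abundances are shaped by
drift, immigration, and speciation alone? Neutral theory supplies an exact
null model for this question, testable sample by sample from nothing more
than each sample's species abundance vector.

`neutralsad` implements that test for samples-by-taxa count tables (mothur
`.shared` or plain TSV), stratified into treatment groups — in the motivating
setting, subgingival plaque samples from healthy subjects and from
periodontitis sites with and without bleeding on probing (BoP).

## The model and the test

For an abundance configuration $D = (n_1 \ge \dots \ge n_S)$ with
$J = \sum n_i$ reads:

* **Ewens sampling formula** (no dispersal limitation, $m = 1$):
  $\Pr(D \mid \theta, J) = \dfrac{J!\,\theta^S}{\prod_i n_i \prod_a \phi_a!
  \prod_{k=1}^J (\theta + k - 1)}$, with $\phi_a$ the number of species of
  abundance $a$. The MLE of the fundamental biodiversity number $\theta$
  solves $S = \sum_{k=0}^{J-1} \theta/(\theta+k)$.
* **Etienne sampling formula** (dispersal limitation through the
  immigration number $I = m(J-1)/(1-m)$):
  $\Pr(D \mid \theta, m, J) = \dfrac{J!}{\prod_i n_i \prod_j \phi_j!}
  \dfrac{\theta^S}{(I)_J} \sum_{A=S}^{J} K(D,A) \dfrac{I^A}{(\theta)_A}$,
  where $K(D,A)$ sums products of unsigned Stirling numbers of the first
  kind over ancestral immigrant allocations. All of this runs in log space
  (Rcpp) so paper-scale samples ($J \sim 10^4$) are routine.
* **Exact neutrality test**: simulate 100 (or 1000) communities at the
  fitted $(\hat\theta, \hat I, J)$ with a sequential-urn sampler, score
  each with the same formula at the fitted parameters, and refer
  $D = -2(\ell_{\rm obs} - \bar\ell_{\rm sim})$ to $\chi^2_1$; a sample is
  consistent with neutrality when the Benjamini–Hochberg-adjusted p-value
  exceeds 0.05.
* **Group statistics**: per-treatment passing rates with pairwise Fisher
  exact tests, and one-way ANOVA with Bonferroni pairwise contrasts on the
  fitted $\theta$ values.

A synthetic-data module generates study-shaped fixtures (3 treatments of
17/22/22 samples, read depths 500–4000, neutral/niche mixtures with known
ground truth), so the full pipeline is testable with no external data.

## Worked example

Fit one sample, then run a small synthetic study end to end:

```r
library(neutralsad)

fit_ewens(c(150, 80, 45, 30, 21, 15, 11, 8, 6, 5, 4, 3, 3, 2, 2, 1, 1, 1, 1, 1))
#> Ewens sampling formula fit
#>   J = 390, S = 20
#>   theta = 4.316, logL = -29.7282

fx  <- make_fixture(fixture_spec(n_per_treatment = c(Healthy = 8, BoP = 8, NonBoP = 8),
                                 J_range = c(300, 800), neutral_fraction = 1),
                    seed = 1)
cfg <- as_configurations(fx$otu, fx$treatments)
v   <- test_neutrality(cfg, n_sims = 100, seed = 1)

passing_rate_table(v)
#> Neutrality passing rates by treatment
#> # A tibble: 3 × 6
#>   treatment n_samples n_pass pass_rate mean_theta sd_theta
#> 1 Healthy           8      8         1       19.1    11.6
#> 2 BoP               8      8         1       34.7     9.29
#> 3 NonBoP            8      8         1       32.4    10.7
#> Overall: 24 / 24 (100.00%)

theta_group_comparison(v)
#> One-way ANOVA on theta: F = 5.050, p = 0.0162 (n = 24)
#> Bonferroni pairwise comparisons
#>   treatment_1 treatment_2   diff      t  p_raw p_bonferroni
#> 1 Healthy     BoP         -15.6  -2.96  0.0103       0.0310
#> 2 Healthy     NonBoP      -13.3  -2.38  0.0323       0.0968
#> 3 BoP         NonBoP        2.30  0.460 0.653        1
```

Every fixture sample here was generated neutrally, and every one passes the
exact test (24/24; the Fisher tests accordingly find no treatment
differences in passing rates). The generator gives the two periodontitis
treatments higher true biodiversity than the healthy group, and the fitted
$\theta$ recovers that pattern: the ANOVA detects the group effect
(p = 0.016) and the Bonferroni contrasts attribute it to healthy-vs-disease,
not disease-vs-disease. `run_pipeline()` wraps these stages (plus the
Ewens-vs-Etienne formula comparison and TSV report writers); a thin CLI
lives at `inst/exec/neutralsad.R`.

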