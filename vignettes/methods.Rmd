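---
title: "Ensemble SDMs and protected-area gap analysis on synthetic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDMs and protected-area gap analysis on synthetic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmgap)
```

## The scientific problem

Protected areas (PAs) are designated to conserve today's biodiversity, but
whether they will keep covering species' habitats as climates shift is an
empirical question. The standard assessment couples ensemble species
distribution models (SDMs) — fitted to presence records and bioclimatic
predictors, projected to current and future climates — with an overlay of the
resulting habitat maps on the PA network: which fraction of each species'
range is protected now, which fraction of habitat will be lost inside versus
outside PAs, and where do high-richness, climate-robust cells fall outside
any PA (conservation gaps)?

Running that workflow on real data requires millions of occurrence records,
global climate layers and the WDPA polygon database. `sdmgap` implements the
complete analysis pipeline in a form that is *testable without any
download*: a synthetic-world generator produces climates, virtual species
with known niches, biased samples, PA networks and political partitions with
full ground truth, so every stage — and the headline qualitative result —
can be verified end to end on a desk machine. The same functions accept real
rasters and occurrence tables in the package's plain-text formats.

## The synthetic world

**Climate.** Six bioclimatic layers (BIO1, BIO3, BIO5, BIO6, BIO12, BIO18 —
annual mean temperature, isothermality, warm/cold extremes, annual and
warm-quarter precipitation) are generated as spatially autocorrelated
Gaussian-like fields: white noise convolved with a Gaussian kernel on the
torus (FFT), standardized, then mapped to each variable's scale. The
correlation length (`range_km`, default 15 km) controls patchiness.
Temperature ordering is guaranteed by construction — BIO5 and BIO6 are BIO1
plus/minus positive log-normal margins — and precipitation is log-normal
with BIO18 a logistic fraction of BIO12, so
`BIO6 <= BIO1 <= BIO5`, `BIO12 >= 0` and `0 <= BIO18 <= BIO12` hold at every
cell with no rejection sampling.

**Future scenarios.** `project_future_climate()` applies additive and/or
multiplicative per-variable shifts plus optional cell-level noise. The
reference scenario warms all three temperature variables by +2.5 °C and dries
both precipitation variables by 10% — the magnitude of a mid-century
intermediate-emissions pathway relative to the landscape's spatial
variability (BIO1 sd = 5 °C, so the shift is 0.5 sd). With `pa_stability`,
deltas inside PA cells are scaled by a damping factor (default 0.5),
emulating the empirical observation that most PAs sit where climate is
changing more slowly. Because shifting one variable alone could break the
temperature ordering, the projection repairs invariants minimally on the
variables the caller did *not* shift; shifted variables are reproduced
exactly as requested.

**Virtual species.** Each species is a product of per-variable Gaussian
responses `exp(-(x - opt)^2 / (2 sd^2))`, so suitability is 1 at the joint
optimum; cells at or above the presence threshold (default 0.3) form the
true range. The default niche breadth is 0.35 of a layer's spatial standard
deviation, which yields true ranges covering roughly 10–15% of the
landscape. That choice mirrors the empirical situation the pipeline
addresses — amphibian and reptile ranges are small relative to their
calibration regions — and makes "recovering the range" a meaningful test;
with much broader niches a species occupies most of the background and
presence/background discrimination is ill-posed for any method. Recovery
quality is insensitive to the exact value across 0.30–0.45.

**Occurrence sampling.** Records are drawn cell-wise with replacement with
probability proportional to suitability × effort, emulating raw presence-only
archives before de-duplication. The default effort surface declines
west-to-east 3:1 — sampling effort in real archives is strongly uneven — and
is a free parameter, not an estimate of any real effort field.

**PA network and partitions.** PAs grow as contiguous patches by seeded
flood-fill to a target protected fraction (default 15% in ~25 patches), each
patch carrying one IUCN class (Ia–VI) drawn from a configurable mix;
`placement = "stable"` seeds and grows patches preferentially in cells with
the smallest projected |ΔBIO1|, reproducing the "PAs occupy climate-refugial
land" mechanism. Zoogeographic regions and countries are connected
multi-source random-growth partitions of the grid.

## Occurrence preparation

Filters apply in a fixed order, because order changes counts: (1) records
farther than 400 km (Euclidean point-to-polygon distance) from the species'
known range polygon are removed — distance exactly 400 km is kept; (2)
records within a radius of blacklisted coordinates (capitals, museums) are
removed and exact coordinate duplicates collapse to the first record; (3)
spatial thinning retains exactly one record — the first in input order — per
1 km grid cell; (4) species keep a model only with at least 5 thinned
records (inclusive). Every removed record carries exactly one removal
reason, so input count = kept + removed always. Thinning is idempotent. A
record falling outside the grid extent is flagged with its own
`outside_grid` reason rather than mislabelled. Within-cell retention is
deterministic (first record) rather than randomized; this is a documented
choice where common thinning tools randomize.

## The ensemble SDM

`ensemble_sdm()` is the package's central fitting function; it returns a
classed object with `print`, `summary`, `predict` and `plot` methods.

1. **Calibration area**: cells in zoogeographic regions occupied by at least
   one presence *and* within 500 km of a presence-cell centre. Cells outside
   it are unsuitable by definition and are never scored.
2. **Collinearity screening**: stepwise VIF on a random sample of
   calibration cells (default 10 000, capped at availability; the sampling
   domain is configurable because the choice — presence cells, calibration
   cells, whole layer — is a genuinely open methodological point). The
   variable with the largest VIF is removed repeatedly until all remaining
   VIFs are below 10; ties break by the stack's variable order; perfect
   collinearity reports `Inf` rather than failing.
3. **Pseudo-absences**: uniform draws without replacement from calibration
   cells minus presence cells. The count is `max(n_presence, 1000)` by
   default — presence-only modelling needs an explicit background size and
   this common convention is surfaced as a parameter because results depend
   on it.
4. **Replication**: five stratified 70/30 train/test splits (training size
   `round(0.7 n)` overall, both labels guaranteed on both sides).
5. **Base learners**: GLM (binomial), gradient-boosted trees (60 rounds,
   depth 3, learning rate 0.1), a MaxEnt-style lasso-regularized logistic
   regression on linear + quadratic features, a probability random forest
   (200 trees), and a radial-kernel SVM whose decision values pass through
   the logistic function — a monotone map to (0, 1) that preserves
   rank-based metrics and thresholds while avoiding a randomized internal
   calibration step. All hyperparameters live in one versioned spec list.
   Constant predictor columns are dropped with a message. Every fit is
   deterministic under the fit seed.
6. **Evaluation and retention**: each algorithm × replicate run is scored on
   its test split by AUC (midrank statistic, equal to the all-pairs
   probability with ties counting half) and TSS maximized over candidate
   thresholds. Runs below TSS 0.7 are discarded; retention is per run, not
   per algorithm-mean (a config-visible choice, since the criterion is
   ambiguous between the two).
7. **Ensemble and binarization**: retained runs are averaged with weights
   proportional to their TSS. The final maxTSS threshold is computed on the
   pooled presence/pseudo-absence set scored by the ensemble — the
   reproducible choice when no evaluation split is singled out — with
   `score >= threshold` mapping to presence, and the smallest threshold
   returned among ties.
8. **Future projection** (`project_range()`): a cell is suitable in the
   future only if it clears the same threshold under future climate *and*
   is occupied currently — the no-dispersal assumption appropriate for
   low-vagility ectotherms. A species with no remaining cell is flagged
   extinct; a species with no retained run is flagged unmodelable and
   excluded downstream with a logged status.

## PA-effectiveness statistics

Per species: protected range fraction under the strict (IUCN Ia–IV) and all
(Ia–VI) PA subsets (inside + outside = 1 exactly); percent loss of current
range cells inside and outside PAs (a stratum with no current cells is
excluded from that stratum's sample). Across species: the percentage with at
least one protected cell (extinct species leave the denominator in future
scenarios); the share whose protected fraction strictly exceeds the 15% and
30% benchmarks; and rarity-weighted richness (RWR) in two modes — the
species-sum of inverse range sizes over species occurring in PAs, and a
cell-sum raster whose total over all cells equals the species count exactly.
Both modes ship because the two-step verbal definition does not fix the
aggregation; the package documents rather than resolves that ambiguity.
"Occurring in PAs" means one or more range cells in the subset; any area
threshold would be an invention.

Inside-versus-outside loss is compared with a paired Wilcoxon signed-rank
test (same species, two strata): zero differences dropped, average ranks for
ties, exact distribution (generating-function convolution over sign
assignments) at 12 or fewer non-zero pairs, otherwise a tie-corrected,
continuity-corrected normal Z. Current-versus-future coverage compares
different species sets (extinct species are gone from the future), so it
uses the unpaired rank-sum variant.

## Priority and gap mapping

Cell-level species richness and percent species loss
(`100 (rich_now - rich_future)/rich_now`; zero-richness cells masked) are
classified into deciles with type-1 (inverse-empirical-CDF) quantiles so bin
edges are bit-exact across platforms; ties fall to the lowest admissible
bin. Priority cells have richness at or above the 80th percentile *and*
loss at or below the 20th percentile of valid cells (boundaries inclusive);
gaps are priority cells outside the PA network. Quantiles are taken over
valid (non-masked) cells, not all land cells, because loss is undefined at
zero richness; the choice is configurable. Country-level accounting divides
each country's gap-cell area by its total area; gap areas sum to the total
gap area by construction.

## Orchestration and reproducibility

`validate_config()` resolves a nested configuration against documented
defaults, rejecting unknown keys and out-of-range values with messages that
name the key. `run_pipeline()` executes the stages `simulate`, `prep`,
`sdm`, `assess`, `gaps` (or any suffix of that order against cached state),
writes plain-text artifacts — CSV tables, ESRI ASCII grid rasters, JSON
status and manifest — and logs line-delimited JSON events. Every random draw
derives from the master seed through a per-stage, per-species hash, so
adding a species never perturbs another species' results, and re-running an
identical configuration reproduces identical artifact checksums. Rasters use
the ESRI ASCII grid format: a plain-text, header-carrying raster
interchange format that any GIS reads.

A small worked run (grid sizes and species counts are the package's desk
defaults; the full reference configuration is `default_config()`):

```{r example, eval = FALSE}
cfg <- validate_config(list(
  grid = list(n_rows = 60L, n_cols = 60L),
  species = list(n_species = 6L, n_occurrences = 150L),
  pa = list(n_patches = 8L),
  partition = list(k_regions = 3L, k_countries = 4L),
  sdm = list(n_vif_cells = 2000L, n_pa = 400L),
  seed = 7L))
res <- run_pipeline(cfg, out_dir = tempfile("sdmgap"))
res$results$assessment$tests
```

## What passing tests do and do not show

The generator emulates the *statistical character* of the real inputs —
autocorrelated climate, niche-driven ranges, uneven sampling, patchy PAs —
not their geography: there are no coastlines, no projection distortions, no
land-use covariates, and sampling bias is a free parameter rather than an
estimate of real collection effort. Passing the recovery and mechanism tests
therefore shows the pipeline's machinery is correct and that the
PA-refuge mechanism (damped climate change inside PAs ⇒ lower habitat loss
inside ⇒ rising protected fractions) propagates through it; it does not
validate any real-world magnitude. Real-data magnitudes depend on inputs the
package deliberately does not bundle.

## Numerical choices and limitations

- Binarization, benchmark and buffer boundaries are pinned (`>=` threshold,
  strict `>` benchmarks, `>` buffer removal) so counts are bit-exact.
- Type-1 quantiles everywhere a quantile feeds a set definition.
- Exact collinearity reports `Inf` VIF; the filter never raises on it.
- The SVM's logistic-of-decision-value scores are calibrated only up to a
  monotone map; TSS-threshold-based binarization is invariant to that, but
  the ensemble average mixes it with probability-calibrated learners —
  acceptable for TSS-weighted consensus, noted for users who want calibrated
  suitabilities.
- Virtual-species recovery is evaluated by Jaccard overlap with the true
  range; the desk-scale experiments use 150 × 150 grids with 200 thinned
  presences and the mechanism experiment 200 × 200 with 30 species — sizes
  chosen as the package's reference desk conditions.
- `filter_years()` exists for real archives (e.g. 1970–2022 windows) and is
  off in synthetic mode, where years are arbitrary.
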