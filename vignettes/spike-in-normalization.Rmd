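---
title: "Spike-in calibrated normalization of multiplex-PCR TCR repertoires"
author: "otsp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in calibrated normalization of multiplex-PCR TCR repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otsp)
```

## The problem

Multiplex-PCR TCRβ assays amplify rearranged loci with 20 Vβ forward and
13 Jβ reverse primers in one reaction. Every one of the 260 V × J primer
pairs has its own amplification efficiency, so the count of a clonotype
after 35 PCR cycles confounds its true abundance with the efficiency of
the pair that amplified it. Rather than iteratively rebalancing primer
concentrations, the protocol this package implements *measures* the bias
with spike-ins: an equimolar mix of 260 synthetic templates (ST), one
per primer pair, each a 200-bp construct carrying a universal 9-bp
barcode (identifying a read as an ST) and a pair-specific 16-bp barcode
(identifying which ST). Because the ST went through the same reaction as
the genomic DNA, their relative counts estimate the relative pair
efficiencies directly.

## Demultiplexing model

A merged read is an ST if and only if the universal barcode occurs
somewhere in it, in either orientation, within one Levenshtein edit
(substitution, insertion or deletion; `N` bases never match). Among ST
reads the template is the 16-bp barcode with the minimal edit distance
over all windows of the read, accepted when that minimum is at most one
edit and a single template attains it; no qualifying template, or a tie
between distinct templates, makes the read *ambiguous* and it is dropped
from both streams (dropping is conservative; ambiguous reads are counted
in the demux summary). ST and ambiguous reads never reach clonotype
calling.

Design notes, where the protocol description leaves room:

* **Orientation.** The universal barcode is searched in the read and its
  reverse complement. Orientation is *not* decided solely by which
  strand shows a universal hit: a random 150-mer contains a spurious
  within-one-edit 9-mer match with probability of a few percent, so a
  reverse-complement ST read will occasionally also show a forward hit.
  The 16-bp assignment therefore considers both orientations; the
  correct barcode wins on distance. Without this, ~2% of error-free
  reverse-complement reads would be lost as ambiguous.
* **Localization.** The 16-bp barcode sits immediately after the
  universal barcode in the construct, so a ±4-nt window around the
  matched position is tried first and accepted only on a unique exact
  hit; anything else falls back to the full scan. This is purely a fast
  path — it cannot change the result, only short-circuit it.
* **Tie-breaking.** The library generator enforces pairwise edit
  distance ≥ 3 between unique barcodes, so at one allowed edit two
  templates can never both qualify for the same window; the tie branch
  guards corrupted or foreign libraries.
* **Quality scores** are not used; upstream read QC and merging are out
  of scope for the package.

The inner scan is a small C++ dynamic program over window end positions
(free start, free end), because per-read pattern matching through
R-level calls is two orders of magnitude too slow for whole samples. The
test suite checks the implementation against an exhaustive
`adist`-over-all-windows oracle read by read.

## Count model

For one template across $n$ replicate ST-only samples, counts are
modelled as negative binomial in mean/overdispersion form,

$$C \sim \mathrm{NB}(m, d), \qquad E(C) = m, \quad
\operatorname{var}(C) = m + d\,m^2,$$

so $d = 0$ is the Poisson boundary and on a log–log mean–variance plot
the large-$m$ behaviour is a line of slope 2 at height $\log d$. Note
$d$ is the reciprocal of the conventional NB `size`; the package states
this parameterization everywhere to avoid the usual ambiguity.

* The mean MLE is the arithmetic mean of the replicate counts (closed
  form in this parameterization); `fit_nb()` returns it exactly, never a
  numerically optimized copy.
* The dispersion is the profile MLE at the fixed mean, found by bounded
  scalar optimization on $[0, 50]$ (golden-section via `optimize()`,
  tolerance $10^{-8}$), with the method-of-moments value
  $\max(0, (\hat v - \hat m)/\hat m^2)$ as a sanity anchor and the
  boundary $d = 0$ checked explicitly so zero-variance data lands on the
  Poisson boundary exactly.
* All-zero rows are degenerate (no likelihood information): flagged,
  assigned $m = d = 0$, and excluded from the common-dispersion median
  with a warning.
* The common dispersion is the *median* of the 260 per-template fits.
  At calibration scale ($n = 20$) the profile MLE is biased low by
  roughly 10% (the usual $1/n$ variance bias: simulations at true
  $d = 0.125$ recover medians around 0.110–0.115). The package reports
  the estimate as computed; no bias correction is applied, matching how
  the published calibration value was itself obtained.

## Scaling factors and normalization

Write $C_{i\bullet}$ for template $i$'s batch mean and
$C_{\bullet\bullet}$ for the grand mean of the 260 batch means. The
batch-mean factor is $SF_i = C_{i\bullet}/C_{\bullet\bullet}$; the
NB-mean factor is $m_i/m_\bullet$. Both sets average to exactly 1 by
construction (asserted to $10^{-12}$ in the tests), and they coincide
elementwise on the same matrix because $\hat m_i = C_{i\bullet}$. The
NB-mean form matters operationally: factors estimated once from ST-only
batches can normalize later samples sequenced *without* spike-ins.

Normalization of a clonotype table proceeds pair-wise: aggregate counts
to primer-pair totals through a user-supplied gene→primer map (panels
are many-to-one; the map is deliberately not hard-coded so other primer
panels can be calibrated), divide each total by its factor, and give
each clonotype its raw within-pair proportion of the normalized total.
Consequences, all tested as exact identities:

* within-pair proportions, ratios and ranks are invariant;
* batch-mean self-normalization preserves the ST grand total exactly;
  NB-mean normalization preserves it in expectation;
* normalized counts are real-valued — they are never re-rounded, since
  rounding would break both identities and all downstream metrics use
  frequencies anyway.

Templates with zero estimated mean get no factor; normalizing a nonzero
total against a flagged pair is a loud error rather than a silent
pseudocount, which would quietly distort the identities above.

Pooling calibration batches sequenced at different ST concentrations
("combined estimates") is done by reducing each batch's mean vector to
relative frequencies, averaging with weights proportional to batch
sample counts, and rescaling so the grand mean equals the weighted mean
of the batch grand means. This is the minimal rule that is invariant to
per-batch concentration rescaling; the original protocol's exact pooling
estimator is not public, so this documented stand-in is used. Cross-batch
stability is summarized as the Pearson correlation of *log* factors
(natural log; the base cancels in $r$).

## V × J dependence

Pooled over samples, the 260 ST counts form a 20 × 13 contingency table.
Signed Pearson residuals $(O - E)/\sqrt{E}$ with
$E = (\text{row total} \times \text{column total})/\text{grand total}$
quantify departure from independent primer contributions; the sum of
squared residuals is the chi-squared statistic (checked against
`chisq.test` as an oracle). Average-linkage hierarchical clustering on
Euclidean distances orders rows and columns for display; when all
pairwise distances tie (e.g. a zero residual matrix) the input order is
kept, making the ordering deterministic.

`independence_null_spread()` answers "how flat could normalized counts
possibly look if templates were truly iid NB$(m,d)$?" by Monte Carlo:
draw an iid matrix, self-normalize with its own batch factors, record
each sample's spread of normalized counts (log max/min ratio and IQR of
logs). Two properties of this null are worth stating because one of them
is easy to get backwards:

* spread grows stochastically with $d$ (Poisson draws are flatter);
* under **self**-normalization the spread converges to the
  single-sample NB sampling floor *from below* as the number of samples
  grows: with few samples the factors partially fit the very noise they
  are dividing out, shrinking the apparent spread. The test suite
  asserts convergence toward the floor, not a monotone decrease.

## The synthetic-data generator

The generator is first-class, tested code; it states the world the
acceptance checks run in.

**Bias model.** Pair $(v, j)$ has relative efficiency
$\exp(\alpha_v + \beta_j + \gamma_{vj})$ with centred normal components.
Defaults $\sigma_\alpha = \sigma_\beta = 0.6$,
$\sigma_\gamma = 0.2$ produce a multi-fold ST-to-ST spread comparable to
an uncalibrated panel; they are stated once here and not tuned. The
implied true scaling factors have mean exactly 1.

**ST-only matrices.** Template $i$ has mean
$\mu_i = \text{depth} \cdot w_i / \sum w$; the default depth of
260 × 1000 gives calibration-scale counts, $d$ defaults to 0.125, and
$n = 20$ samples matches the reference calibration batch. Two sampling
schemes share these NB marginals:

* `independent` (default): every count an independent NB draw — the
  textbook model the fitting code assumes;
* `library`: one NB library total per sample, allocated multinomially.
  Binomial thinning of an NB leaves $d$ unchanged, so per-template
  marginals are *identical* to the independent scheme, but the
  overdispersion becomes common-mode within a sample.

The second scheme exists because real calibration batches behave that
way: template counts rise and fall together across samples, and their
joint behaviour is demonstrably not independent — which is precisely why
normalization can beat the iid lower bound. Simulating calibration
batches as `library` and fitting them as independent NB is not a
contradiction; the marginal law being fitted is the same. The 50:50
mixture acceptance check calibrates on `library` batches for this
reason: with iid calibration noise the factor-ratio error has a hard
floor of $\sqrt{2d/n_{\text{eff}}}$ ($\approx 0.08$ even pooling 40
samples), which makes "strictly closer to ½ in ≥ 95% of replicates" a
knife-edge claim (~94–96% measured); with common-mode calibration noise,
as in real batches, the criterion holds with margin (97.5–100% across
seeds).

**Experiments.** A sample is one NB total split multinomially between ST
templates (share proportional to `st_mass`) and clonotypes (share
proportional to `gdna_mass`), with clonotype weights equal to true
abundance × pair efficiency. This encodes the protocol's central working
assumption — clonotypes inherit exactly the bias of their primer pair —
and a `bias_mismatch_sd` knob adds clone-level log-normal departures to
stress-test it. Spike-in/genomic competition and clone dropout emerge
naturally: raising `st_mass` at fixed depth starves the clonotype
stream.

**Reads.** One read per counted molecule: ST reads embed the universal
and template barcodes at their construct positions inside 200-nt
sequences; clonotype reads embed the clone's CDR3 between flanks that
are re-drawn until they contain no within-one-edit universal-barcode
window (otherwise a few percent of clonotype reads would be emitted
pre-contaminated). Substitutions are applied per base; an optional
single indel per read exercises the demultiplexer's edit tolerance; half
the reads are emitted reverse-complemented. With zero error rate,
demultiplexing recovers the ST counts exactly — asserted as an identity,
not a tolerance.

What the generator does *not* emulate: PCR-cycle chemistry, chimeras,
quality-score structure, or clonotype-caller errors (clonotype calling
is consumed as upstream TSV). A green suite therefore establishes the
statistical logic of the calibration, not the behaviour of any
wet-lab instrument.

## Repertoire metrics

On frequencies $p_k$ (from normalized counts when present):
Shannon diversity $H = -\sum p_k \ln p_k$; clonality $1 - H/\ln S$
(0 = even, → 1 = monoclonal; defined as 1 with a warning for $S = 1$);
maximum clonal frequency; hyperexpanded fraction
$\sum_{p_k > t} p_k$ with default threshold $t = 0.01$. The clonality
and hyperexpansion definitions follow common field usage; the upstream
literature defers their exact formulas to secondary sources, so they are
stated here explicitly as the package's definitions. All metrics depend
on frequencies only, hence are invariant under uniform count rescaling;
primer-pair normalization moves them only through pair weights.

## Numerical and degenerate-input policy

* Seeds are mandatory for every stochastic operation; pipeline stages
  derive sub-seeds deterministically and record them in the run
  manifest, so reruns are byte-identical.
* Dispersion search interval $[0, 50]$; boundary estimates return
  exactly 0.
* Sample variances use the $n - 1$ denominator.
* Empty inputs: empty read sets demultiplex to zero vectors; empty
  clonotype tables aggregate to zero totals; empty frequency vectors are
  errors.
* Unmapped genes route to a reported "unmapped" bucket and are excluded
  from normalization rather than guessed.

## Known limitations

* The pooling rule for combined estimates is a documented stand-in, not
  the original (non-public) estimator.
* Clonality/hyperexpansion formulas are explicit package definitions;
  concordance with other platforms' "clonal index" is expected to be
  monotone, not identical.
* The common-dispersion estimate inherits the small-sample MLE bias
  (~10% low at $n = 20$); consumers comparing calibrations at different
  $n$ should be aware of it.
* Read emission models substitutions and single indels only; highly
  degraded libraries (adapter read-through, chimeric merges) are outside
  the generator's world.
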