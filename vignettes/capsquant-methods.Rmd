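---
title: "Methods: restriction-site discrimination of paralogs and growth-based transporter kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restriction-site discrimination of paralogs and growth-based transporter kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsquant)
```

# Scope

`capsquant` implements two quantitative procedures around the functional
characterisation of redundant transporter paralogs: a CAPS-style (cleaved
amplified polymorphic sequence) workflow that discriminates and quantifies
near-identical transcripts from restriction digest band patterns, and a
growth-constant workflow that estimates a heterologously expressed
transporter's apparent substrate affinity from complemented-yeast growth
curves. This vignette records the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic-data generators do
and do not emulate.

# Restriction discrimination

## Model and conventions

A restriction enzyme is described by its top-strand recognition motif
(IUPAC alphabet) and a cut offset in bases from the motif's 5′ end:
ClaI = `AT^CGAT` has offset 2. Coordinates are 1-based and a cut at
coordinate $c$ splits $[1..c]$ from $[c+1..L]$, so $c$ equals the length of
the prefix fragment; a motif match starting at $p$ cuts at
$c = p + \mathrm{offset} - 1$. This convention makes the arithmetic of the
reference geometry exact: a 1959-bp variant "cut 1752 bp downstream of the
start codon" yields fragments 1752 + 207, and cutting at 1098 and 1752
yields 1098 + 654 + 207. Whether a published coordinate refers to the cut
position or the motif start is in general ambiguous; we adopt the cut
position because only it reproduces the printed fragment lengths without a
correction term.

Digestion is of linear molecules (the assay digests PCR amplicons);
circular templates and partial digestion are out of scope. Cuts that would
fall at coordinate 0 or $L$ are discarded — they would create zero-length
fragments, which no gel can show. Palindromic motifs are scanned on the top
strand only (their bottom-strand occurrence coincides); non-palindromic
motifs are additionally searched as their reverse complement, with the cut
mapped back as $c = p + (m - \mathrm{offset}) - 1$. Ambiguity codes in a
*motif* match the base set they denote; ambiguity codes in the *sequence*
never match anything — the conservative choice for assay design, since a
site that may or may not be cut is useless as a marker.

## Band classification

Fragments co-migrate when a gel cannot separate them. We cluster all
fragments of all variants by single linkage on relative length difference
$|l_1 - l_2| / \bar{l}$ and cut the dendrogram at a tolerance whose default,
0.02 (2%), approximates routine agarose resolution; it is configurable, and
tolerance 0 classifies by exact length. Single linkage is the physically
right choice: co-migration is a chain relation on a gel lane. A band class
is *diagnostic* when all its member fragments come from one variant. Bands
under 50 bp are flagged as likely undetectable but still enter the
arithmetic. `screen_enzymes()` scores each enzyme in a table by how many
variants receive at least one diagnostic band — note that an uncut variant
still yields its full-length band, so distinct uncut lengths beyond the
tolerance discriminate on their own.

# Gel quantification

## Intensity model

For an intercalating stain the band signal is proportional to DNA mass,
i.e. molar amount × fragment length. Writing $M$ for the band-by-variant
*incidence matrix* — entry $M_{bv}$ is the summed length of variant $v$'s
fragments in band class $b$, so columns sum to variant lengths — a lane's
expected intensities are $y = M a$ for molar abundances $a$. Two inverses
are provided:

* **diagnostic** (the assay as published): each variant's molar signal is
  the mean over its diagnostic bands of intensity / mass entry; shared
  bands are ignored, exactly as a band shared between two variants gives
  "no result useful" for telling them apart. Requires every variant to own
  at least one diagnostic band, and says so by name when one does not.
* **least_squares** (a documented extension): nonnegative least squares of
  $y \approx M a$ using *all* bands, shared ones included. The solver is a
  small Lawson–Hanson active-set implementation (no NNLS routine ships with
  the available dependency stack); problems are a handful of bands by a
  handful of variants, far below any numerical-conditioning concern. On
  noise-free data both modes agree to numerical precision, which the test
  suite uses as a dual-route check.

Molar signals are divided by the lane's loading-control intensity, which
makes the result invariant to overall lane brightness (scale equivariance
is property-tested). No background subtraction is applied — supplied
intensities are taken as already background-corrected by the upstream
densitometry; mass-vs-molar reporting is fixed to the molar convention by
the division by length.

## Replicates and statistics

The reference experimental design is three biological replicates each
measured in technical triplicate ($n = 9$). Technical replicates are
averaged within their biological replicate before any averaging or testing
(`quantify_lanes()` does this when lanes carry a `bio` label), avoiding
pseudo-replication; the exact nesting of the published error term is not
stated, so biological-replicate means are the default and the per-lane
table remains available. Percent change versus control is
$100(\text{treated}/\text{control} - 1)$. Group comparison uses pairwise
two-sample Student's t-tests with the Bonferroni-corrected threshold
$\alpha/m$ over the $m = g(g-1)/2$ pairs (inclusive comparison, matching a
"$P \le$" significance convention), plus compact-letter display via
insert-and-absorb. Zero-variance identical groups compare as
non-significant rather than erroring.

# Growth kinetics

## Model

Complemented yeast growing on its sole sulfur source at external
concentration $S$ is modelled as exponential,
$A_{600}(t) = A_{600}(t_0)\,e^{kt}$, with duplication time
$dt = \ln 2 / k$ and growth rate $dt^{-1} = k / \ln 2$. The
rate-versus-substrate isotherm follows a Michaelis–Menten hyperbola
$\mathrm{rate}(S) = k_{max} S / (k_G + S)$; $k_G$, the concentration at
half-maximal growth rate, approximates the transporter's $k_M$ under
transport limitation. Published growth rates are in $dt^{-1}$; whether a
rate is expressed as $k$ or $k/\ln 2$ only rescales $k_{max}$, and $k_G$ is
invariant to the convention — which is why that ambiguity is safe.

## Exponential-phase selection

With an explicit window, $\log(\mathrm{od})$ is regressed on time over it.
Otherwise the window is auto-selected: the longest contiguous run of at
least 4 points with log-linear $r^2 \ge 0.98$ (ties to the higher $r^2$),
then a boundary refinement that drops an end point while doing so explains
more than 20% of the remaining misfit $1 - r^2$. The refinement exists
because the bare longest-run rule happily swallows a shallow lag whenever
the pooled window still clears 0.98 — the wide dynamic range of an
exponential keeps $r^2$ high even with a few flat leading points — which
biases $k$ low; trimming while the gain is substantial removes exactly
those points and reduces to the bare rule on clean data (on noise-free
curves the gain is zero and nothing is trimmed). Both knobs (minimum
points, $r^2$ threshold) are exposed; the source protocol states no window
rule. A flat series (zero log-variance) returns $k = 0$ rather than an
undefined $r^2$; a series with no qualifying window raises "no exponential
phase detected". No blank is subtracted by default (optional constant
blank).

## Isotherm fit

Replicate curves are fitted independently; rates are averaged per
concentration (mean ± SE), matching a means-of-replicates design, and the
isotherm is fitted by nonlinear least squares (`nls`, `port`, positivity
bounds) weighted by inverse variance when SEs are available. Initial values
come from the Hanes–Woolf linearisation $S/v = S/k_{max} + k_G/k_{max}$,
which is exact on noise-free data — so exact-recovery tests at $10^{-6}$
relative tolerance are meaningful. Standard errors come from the fit
covariance (linearisation). The $S = 0$ culture is excluded from the fit by
default: residual growth without substrate reflects internal stores, not
transport; its rate is pinned at 0 in the reported isotherm (a flat noisy
curve has no exponential phase, and for $S = 0$ only, that outcome maps to
rate 0). With fewer than 4 distinct concentrations the fit warns but
proceeds; on a two-point low-substrate design the individual parameters are
barely identified yet their ratio — the low-S slope $k_{max}/k_G$ — is
exact, which the tests check.

The affinity classification boundary defaults to 100 μM, inclusive:
group-1 high-affinity sulfate transporters sit in the low-micromolar range
while low-affinity carriers sit in the hundreds of micromolar, so any
boundary in between separates them; 100 μM is the highest concentration of
the reference ladder.

## Transport-limitation checks

$k_G \approx k_M$ needs growth to be uptake-limited. Three observable
conditions are encoded: the internal substrate store per $A_{600}$ unit
shows no significant monotone trend across external concentrations
(Spearman rank correlation, $\alpha = 0.05$; absence of significance is the
pass condition, so this is a sanity check, not proof of flatness); growth
on an organic source of the nutrient is strictly faster than at the highest
substrate concentration (downstream assimilation is not the bottleneck);
and the starvation ($S = 0$) store is below 0.05 nmol per $A_{600}$ unit
(stores cannot fuel growth). A missing organic-source control renders that
check indeterminate and the overall verdict invalid, with the reason
recorded.

# Synthetic data: the stated world

`make_paralog_set()` builds the reference trio over a shared uniform-random
background: variant_c (1959 bp) carries ClaI sites cutting at 1098 and
1752; variant_b keeps only the 1752 site; variant_a is variant_b with its
site destroyed and a 9-bp insertion placed immediately after the start
codon (the published insertion sits at the 5′ end of the coding sequence),
giving 1968 bp and no site. Unintended motif occurrences are destroyed by
deterministic single-base edits and the result is rescanned: the geometry
is guaranteed exact, byte-reproducibly per seed. There is no substitution
process or codon structure — the generator emulates cut-site geometry, not
molecular evolution, so green digestion tests establish coordinate
arithmetic and band logic, not anything about real sequence divergence.

`simulate_growth()` is the mechanistic forward model of the growth assay:
Michaelis–Menten-limited exponential growth, defaults copying the reference
design — concentration ladder 0, 1, 2.5, 5, 7.5, 10, 25, 50, 100 μM, hourly
readings for 25 h, inoculum $A_{600} = 0.1$, 6 replicates (two experiments
in triplicate). Measurement noise is multiplicative log-normal (absorbance
error scales with signal) with sdlog 0.02 by default; the real
inter-replicate scatter is not reported, so 2% is a stated assumption, not
a fitted one. An optional logistic plateau exists because real cultures
saturate, but defaults off so that analytic recovery is exact. Edge
effects, evaporation and reader drift are not modelled.

`simulate_lane()` draws band intensities as the incidence-matrix product
times log-normal noise (default sdlog 0.05, likewise an assumption) and
noises the reference amplicon the same way. The maximal growth rate
$k_{max}$ used when simulating the published assay is 0.35 dt⁻¹ h⁻¹
(saturating doubling time ≈ 2.9 h, realistic for a complemented yeast on
minimal medium); the published isotherm figures were not machine-readable
here, and $k_G$ recovery is invariant to $k_{max}$, which only rescales the
isotherm.

Every simulator is seed-deterministic, restores the caller's RNG state, and
serves as its own oracle: estimators applied to noise-free simulator output
recover the generating parameters to $10^{-6}$ relative tolerance, which
the acceptance suite asserts. Under the stated world (2% OD noise), 200
simulated assays give a median relative $k_G$ error of about 0.2% and
nominal-95% CI coverage of about 92% — comfortably within the ≤ 10% error
and ≥ 85% coverage the estimator is required to achieve; these numbers are
recomputed by the test suite, not quoted from anywhere.

# Known limitations

* Band classification is geometric; it does not model smiling, partial
  digestion, heteroduplexes, or stain saturation.
* The diagnostic-mode error model treats each diagnostic band as an equally
  reliable estimate; weighting by band mass would be straightforward but is
  not published practice.
* The auto-window rule, though refined, can still retain one or two
  near-exponential lag points when noise is very low and the lag is
  shallow; an explicit window overrides it.
* The Spearman flatness check has low power at 3–5 concentrations; it
  guards against gross assimilation bottlenecks, not subtle ones.
* The CLI validates its own flags but is deliberately thin; programmatic
  use of the exported functions is the primary interface.
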