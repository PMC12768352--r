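---
title: "Profiling dsRNA-derived siRNAs and screening for secondary amplification"
author: "siRNAscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling dsRNA-derived siRNAs and screening for secondary amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siRNAscreen)
```

## The problem

Injecting long double-stranded RNA (dsRNA) into an animal that expresses the
matching transgene triggers RNA interference: Dicer processes the trigger
into short interfering RNAs (siRNAs) which silence the transcript. Two
questions dominate the analysis of the resulting small-RNA sequencing
libraries. First, *what do the trigger-derived siRNAs look like* — their
size distribution, strand of origin, positional coverage on the target,
phasing register, and nucleotide composition. Second, *is the response
amplified*: several invertebrates and plants synthesize secondary siRNAs de
novo (via RNA-dependent RNA polymerases, RdRps), which map outside the
trigger, often carry a 5'-triphosphate, and can shift the size distribution.
In a basally branching animal where none of this is established, the
analysis has to be able to return a confident *negative*: a set of screens
whose operating characteristics — power when amplification is present,
specificity when it is absent — are known.

That is what this package provides: the target-mapped quantification
pipeline (assignment, normalization, per-library metrics), the three
amplification screens plus an Argonaute-loading comparison, the companion
quantitative analyses (comparative-Ct, western-band and fluorescence
summaries, miRNA count filtering, test battery), and — because public raw
libraries are not assumed — a dicing simulator that generates replicate
libraries with per-read ground truth so that every stage can be verified.

## The pipeline

### Read assignment

Reads are collapsed to unique sequences with multiplicities, length-filtered
to 18–30 nt (reads shorter than 18 nt are discarded), and assigned to
exactly one compartment in a fixed precedence: spike-in, mature miRNA,
genome proxy, then target. The genome-before-target order reproduces
genome-subtractive mapping of a transgene: a read that matches the genome is
never counted for the target. Spike-ins and annotated miRNAs are tested
before the genome so that these classes are never absorbed by it; the
precedence is an explicit argument.

Matching is exact, on both strands, implemented with `Biostrings`
dictionaries. A deliberate design choice: the biological claims here rest on
perfectly matching reads, and exactness makes every assignment decision
reproducible by a brute-force oracle (the test suite holds `matchExact` to a
substring/reverse-complement scan on 500 random cases). Mismatch-tolerant
alignment is out of scope. Because only mature miRNA sequences are bundled
(not precursors), the miRNA compartment uses a windowed rule: the read must
align exactly within the mature sequence, with at most 2 unconstrained
nucleotides of 3' overhang — a stand-in for precursor-window quantification.

Coordinates are 0-based half-open throughout; strand `-` means the read
equals the reverse complement of the target slice. Reads that are their own
reverse complement cannot be assigned a strand: they are counted once,
flagged ambiguous, and excluded from strand-resolved outputs. Multi-locus
reads contribute `count / nloci` per locus to coverage; phasing uses
single-locus reads only.

### Normalization

Spike-in normalization divides the raw target count by the mean of the four
per-spike-in counts (each spike-in entered the library at the same fixed
molar input, so the mean tracks library-wise capture efficiency). "Mean of
four" versus "sum of four" differ by a constant factor and change no
comparison; the mean is implemented. RPM needs a denominator convention,
which is genuinely open; the default is all length-filtered reads assigned
to genome + target (spike-ins and unassigned excluded), with
`filtered_total` selectable, and the choice echoed in every output. A
spike-in observed zero times makes spike-in normalization undefined and is
an error rather than an NA; RPM is still available.

### Per-library metrics

* **Size distribution** — multiplicity-weighted counts per length and
  strand; each distinct sequence counted once.
* **Coverage** — per-base depth per strand; total mass equals
  Σ length × count over unambiguous reads.
* **Phasing** — unique (multiplicity-collapsed), single-locus 20–22 nt
  reads; the 5' position of each read, measured on its own strand's 5'→3'
  axis (`start` for `+`, `targetLength − start − length` for `-`), is
  reduced modulo 20 and 21. Processive end-initiated dicing puts each
  strand's reads into one register; internal initiation spreads them.
* **Composition** — positional A/C/G/T frequencies for reads of one length,
  in total (multiplicity-weighted) and unique modes.

Two phasing conventions deserved a decision. Strand handling: registers are
computed per strand on each strand's own axis (Dicer steps along each strand
from its own 5' end), and also pooled by summing the per-strand register
counts; `maxRegisterFraction` is the maximum over per-strand fractions,
because a duplex with a 2-nt overhang places the two strands in different
absolute registers even under perfect processivity. The verdict: "phased"
requires both a pooled chi-square p below 10^-3 *and* a dominant register
(fraction above 2/m). The dominance guard matters because initiation
hotspots alone — reproducible positions with high weight — inflate the
chi-square without any periodicity; requiring a dominant register keeps the
call specific to true phasing. Both thresholds are arguments.

### Secondary-siRNA screens

Each screen returns an effect size, a test, and a categorical verdict
(`signal` / `no_signal` / `underpowered`); any group with fewer than two
replicates is `underpowered` by definition.

* **Upstream screen** — after injecting only the 3' half of the target,
  reads mapping entirely upstream of the injected interval cannot be direct
  dicing products; the per-replicate upstream fraction of target-mapped
  reads (a within-library ratio, so normalization cancels) is compared to a
  tolerance τ = 0.01 by a one-sample t-test. τ absorbs chance multi-locus
  artifacts; with the simulator's decoy noise the null fraction is exactly
  zero, so the default is conservative.
* **RppH contrast** — RdRp products carry a 5'-triphosphate invisible to
  5'-ligation library chemistry; pyrophosphohydrolase (RppH) treatment
  exposes them. Spike-in-normalized target counts are compared across
  treated/mock groups by one-way ANOVA with Tukey HSD contrasts
  (Tukey–Kramer when unbalanced); a replicate-paired t-test is available by
  flag since the enzyme and mock reactions split the same RNA. Capture
  arithmetic fixes the expected effect: with all secondary species
  triphosphorylated and a secondary fraction *s*, the treated/mock ratio of
  normalized counts is 1/(1−s) — the spike-in factor cancels the pool
  renormalization — e.g. 2.0 at *s* = 0.5.
* **Size shift** — nematode-style secondary siRNAs are 22-mers; the screen
  combines the treated−mock difference in per-replicate 22-nt fractions
  with the Jensen–Shannon divergence (natural log, so disjoint supports give
  log 2) between pooled length distributions.
* **Loading enrichment** — for RISC-isolation libraries, the RPM of
  target-mapped reads versus the RPM of the miRNA compartment (after the
  ≥2-reads-in-some-replicate guide filter), paired across replicates.

### Quantitative companions

`ddct()` implements comparative-Ct quantification: ΔCt = Ct(target) −
Ct(reference) per sample, ΔΔCt relative to the *control-group mean* ΔCt
(group-mean convention rather than per-pair matching, fitting n = 3 designs
with group-level t-tests on ΔCt), fold change 2^−ΔΔCt, and percent
knockdown. One-tailed directions are always declared by the caller — a
knockdown hypothesis means "treated ΔCt greater" — never inferred from the
data. `bandNorm()` performs the western double normalization (darkest band
per membrane, then loading-control ratio per lane), with a Shapiro–Wilk gate
(α = 0.05) choosing between t and Mann–Whitney when the caller does not
force one. `fluorSummary()` subtracts background per embryo (clamping at
zero with a warning), averages the 20–30 embryos per image, and compares
replicate means. `testBattery()` exposes the shared test set (one/two-tailed
t, ANOVA + Tukey, Kruskal–Wallis + pairwise Wilcoxon under
Benjamini–Hochberg, Mann–Whitney); constant-variance input is an error for
the parametric routes and proceeds for the rank-based ones.

## The simulator

`simulatePool()` builds a species table — every (5' position, length,
strand) molecule with a relative abundance and truth labels — and
`sampleLibrary()` draws a multinomial library from it. The two seeds have
disjoint roles: `biologySeed` fixes the species set and abundances,
`samplingSeed` only the sequencing draw, so replicate libraries share their
biology, which is exactly what reproducible coverage patterns across
replicates look like.

The generative choices, and what they emulate:

* **Hotspots** — per-position initiation weights drawn once per biology
  seed from Gamma(κ, rate = κ) with κ = 0.5. Small κ gives the heavy-tailed,
  position-stable peaks that make replicate coverage tracks correlate
  (r > 0.9 at the default depth) without imposing any periodicity. The
  observation being emulated is a recurring coverage pattern across
  replicates; no mechanistic model of Dicer site choice is claimed.
* **Strand selection** — per-position sense probabilities from
  Beta(0.5, 0.5): loci tend to commit to a strand, again stable across
  replicates.
* **Lengths** — default mass peaking jointly at 20 and 21 nt (0.27 each),
  the size class of this system's siRNAs, with an 18–30 nt support.
* **Phased mode** — optional processive dicing: 5' ends restricted to a
  step-21 register from each end of the injected interval.
* **Secondary species** — antisense, own length profile (mode 22 nt),
  uniform 5' ends, restricted upstream of the injected interval by default;
  a configurable fraction of their mass carries 5'-triphosphate. The
  `LibraryProtocol` capture mask (standard / RppH / PANDORA-class) filters
  by 5' chemistry before sampling.
* **Background** — mature-miRNA species with a Zipf-like abundance profile
  (rank^−1.1, the steep profile typical of small-RNA libraries); four
  spike-ins at a fixed relative input (0.005 each); and degradation noise
  drawn from a first-order Markov surrogate of the genome proxy, screened so
  that no decoy can be assigned anywhere. The screened decoys are a
  deliberate idealization: they isolate the pipeline's specificity (zero
  noise reads on the target is then a theorem, and the tests verify it)
  rather than model real degradation.
* **Mock libraries** — miRNA background, spike-ins and noise only
  (`targetFraction = 0`); the `targetFraction` knob itself (default 0.55 of
  the pool for an injected library) is a package choice, as the underlying
  design only fixes "enriched versus mock".

What the simulator does *not* model: PCR duplication, adapter read-through,
sequencing error, quality-score realism, or genome-derived degradation that
legitimately maps to the genome compartment. Consequently, passing tests
demonstrate the correctness of the computations and the operating
characteristics of the screens under a clean generative model — not
robustness to mismatches, contamination, or mapping artifacts in real
libraries.

All bundled reference material is synthetic and deterministic: the 720-nt
target stands in for a transgene coding sequence, the genome proxy, matures
and spike-ins are random sequences screened to share no 15-mer with the
target, and the spike-in names follow the conventional four. The Ct table
under `inst/extdata/` is likewise a synthetic stand-in constructed to the
same design as a three-replicate knockdown qPCR (≈40% knockdown); no
measured data ship with the package.

## Numerical choices and problem sizes

* Exactness everywhere: no mismatch tolerance, integer read counts,
  multinomial draws conserve depth exactly.
* Chi-square for phasing is computed from the closed form (no Monte-Carlo
  p-values); registers with zero counts are fine.
* The phasing type-I calibration runs on a 6,000-nt uniform-weight target at
  depth 1,000. The long target keeps the number of *distinct* 20–22-nt
  species far above the number sampled; when unique reads saturate the
  species grid, register counts become hypergeometric rather than
  multinomial and the chi-square turns conservative (deflation by roughly
  1 − sampled fraction). Calibration is therefore performed in the
  dense-support regime; on the 720-nt target the test errs on the
  conservative side, which only strengthens a "no phasing" conclusion.
* Screen characterization (power, specificity, null rates) draws
  per-replicate tallies from the simulator's species-level counts rather
  than re-running sequence assignment inside every Monte-Carlo iteration;
  the exact equality of assignment output with ground-truth tallies is
  established separately, at depth 10^5 over three replicates, so the
  shortcut changes runtime, not evidence.
* Default problem sizes: depth 10^5 for assignment-level checks, 10^4–2×10^4
  for screen-level draws, 200 runs for null-rate estimates, 50 for power —
  sizes at which every Monte-Carlo band used in the tests is stable.
* Degenerate inputs have defined behavior rather than NA propagation: empty
  post-filter pools name the protocol that emptied them; a zero-read phasing
  profile is flagged `undefined`, not an exception; constant data give p = 1
  (identical means) or 0 under the safe t-test wrapper; ties in verdicts
  always fall to the conservative side (`no_signal`).

## Known limitations

* Exact matching means real libraries must be adapter-trimmed and
  high-quality; there is no recovery of reads with sequencing errors.
* The miRNA window (mature + 2 nt of 3' overhang) under-counts isomiRs with
  5' extensions or internal edits, and cannot use precursor context.
* The RppH contrast assumes the spike-ins are unaffected by the enzyme
  treatment; if treatment degraded spike-ins differentially, the
  normalization would absorb a real signal.
* Verdict thresholds (τ = 0.01 upstream, p < 10^-3 with register dominance
  for phasing, JS divergence > 0.01 for the size shift) are explicit,
  documented knobs. They formalize what is otherwise a qualitative call
  ("no secondary siRNAs detected"); there is no established quantitative
  cutoff to calibrate against, so the defaults are choices, not estimates.

## A worked run

```{r, eval = FALSE}
bundle <- syntheticBundle(seed = 42)
config <- defaultSimConfig(bundle, biologySeed = 7, depth = 1e5)
design <- makeDesign(
  groups = list(dsRNA = list(config = config),
                mock = list(config = mockConfig(config))),
  nReplicates = 3)
asg <- lapply(design$libraries,
              function(l) assignReads(libraryReads(l), bundle))
metrics <- libraryMetrics(asg$dsRNA_rep1)
metrics$sizeDistribution$modes        # 20, 21
metrics$phasing$mod21$verdict         # "unphased"

half <- c(360L, 720L)
haCfg <- defaultSimConfig(bundle, biologySeed = 7, depth = 1e5,
                          injectedInterval = half)
haPool <- applyProtocol(simulatePool(haCfg), "standard")
hits <- lapply(1:3, function(r)
  targetHits(assignReads(libraryReads(
    sampleLibrary(haPool, 1e5, r)), bundle)))
upstreamTest(hits, half)              # verdict: no_signal
```

The same computations, at the sizes quoted above, are what
`scripts/acceptance.R` re-runs end to end.
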