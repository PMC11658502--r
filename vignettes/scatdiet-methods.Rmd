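---
title: "Methods: scat metabarcoding diet analysis in scatdiet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scat metabarcoding diet analysis in scatdiet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatdiet)
```

# The problem

A scat collected in the field is a mixed DNA sample: most amplifiable
mitochondrial template comes from the depositing predator, a minority from
prey tissue in transit, and some from degradation products and off-target
amplification. With a short (~100 bp) 12S marker amplified across mammals
and birds, a single sequencing run yields, per scat, a read mixture whose
composition identifies the host and its recent diet. `scatdiet` implements
the full inferential chain — reads, per-scat calls, guild statistics — with
every stage testable against simulations with known truth.

# Read processing and mapping

**Trimming.** Quality trimming uses the modified-Mott rule: with per-base
error probabilities $p_i$ (Phred+33) and limit $L$ (default 0.1), the read
is cut to the contiguous window maximizing $\sum_i (L - p_i)$, found by a
Kadane scan. Reads whose every base exceeds the limit become empty and are
dropped. Trimming is idempotent and always returns a contiguous substring;
both properties are tested.

**Alignment model.** Reads are mapped by Smith–Waterman local alignment
with linear gap costs: match $+1$, mismatch $-2$, insertion (extra read
base) $-3$, deletion (missing reference base) $-3$. The linear model — a
gap of length $g$ costs $3g$ — matches per-operation cost parameters with
no opening/extension distinction; the match score is configurable because
mapping tools typically expose only the costs. Two filters gate a hit:
*length fraction* (aligned read bases / read length, default $\ge 0.9$) and
*similarity* (matching columns / aligned columns, gaps counting as columns,
default $\ge 0.94$). These definitions are the defensible reading of the
vendor-style parameters and both are configuration-exposed. On a ~100 bp
amplicon, the 0.94 bar tolerates up to 6 substitutions, so a reference
library whose taxa differ by $\ge 5\%$ keeps host/prey assignment
discriminative.

**Determinism of tie-breaks.** Co-optimal DP cells are resolved by a fixed
preference (diagonal, then deletion, then insertion; first maximum in
row-major order), so any two implementations of the same convention agree
exactly — the test suite exploits this with an independent plain-R dynamic
program, and cross-checks scores against `Biostrings::pairwiseAlignment`
(gap opening 0, extension 3 reproduces the linear model). Reads tied across
*taxa* ("non-specific matches") are placed by a uniform draw seeded on
(global seed, read id) through a multiplicative hash, making results
reproducible and independent of read order.

**Consensus and rescue.** Reads mapped to one taxon are piled up on
reference coordinates; each covered position takes the plurality base,
exact ties are coded `N`, and identity-to-reference is computed over
covered positions (an `N` never matches). Unmapped or sub-threshold reads
can be rescued de novo: greedy clustering at $\ge 0.98$ identity against
each cluster's founding read, majority-rule consensus per cluster, contigs
kept at length $\ge 100$ with $\ge 2$ supporting reads. Because the
amplicon is one short locus, clustering-plus-pileup replaces overlap-layout
assembly; the conventional 10,000-read coverage bar is kept only as a
`low_confidence` flag. Rescue runs only when a prey candidate failed the
identity threshold or when an assigned scat has no prey call despite a
$\ge 5\%$ unmapped fraction — a handful of stray unmappable reads on an
otherwise resolved scat is background, not a hidden prey item.

# Per-scat decision rules

Host assignment is a total cascade over the read tallies:

1. a sample whose single dominant taxon is a non-predator with at least
   `min_host_reads` reads is **non-target** (e.g. an ungulate dropping
   collected by mistake) — this check must precede the host-read-count
   check, which would otherwise absorb such samples into *undetermined*;
2. fewer than `min_host_reads` (default 50) host-capable reads:
   **undetermined** (degraded sample);
3. one host candidate: **assigned**;
4. exactly two host candidates, no reads on any other prey-capable taxon,
   unmapped fraction $< 5\%$: **intraguild predation**, consumer = the
   larger tally (an exact tie is inconclusive);
5. anything else with $\ge 2$ host candidates: **inconclusive**.

The 50-read cut-off quantifies "insufficient matching reads"; it is not a
published constant and is configuration-exposed. A host-capable taxon only
counts as a *candidate* at $\ge 2\%$ of mapped reads (`min_host_frac`):
without this floor a single stray non-specifically placed read would turn a
clean one-host scat into a spurious two-host pattern. Predators that are
also prey (foxes in a guild with wolves) carry role `both` and participate
on both sides.

Prey occurrences are presence/absence per scat (a taxon counts once per
scat, consistent with the observed maximum of 3 distinct prey per scat).
A prey candidate is accepted when its consensus identity exceeds 0.98
(strict); conflicting candidates — taxa linked by shared read ties — keep
the taxon with most reads, then fewest mismatches. Prey that cannot be
resolved is retained as a countable **Undetermined** category: it appears
in FOO denominators (so occurrence percentages describe everything the
scat contained) but is excluded from biomass, diversity and similarity
computations, which need taxon identities. Each exclusion is
configuration-exposed.

# Dietary metrics

With $r$ the occurrences of a prey item and $R$ the predator's total prey
occurrences, FOO $= r/R \times 100$; host composition is $s/S \times 100$
over scat counts. Biomass uses the feeding-trial regression
$Y = 0.439 + 0.008X$ (kg of prey represented per collectable scat, $X$ the
prey's mean adult mass in kg), with per-prey contribution $Y \cdot n$. The
stated procedure weights a prey item only by its per-scat mass, so small
abundant prey can still dominate; a `mass_weighted` mode
($Y \cdot X \cdot n$) is provided because percentage shares in which large
prey dominate (as intuition expects of "biomass") are only attainable with
mass in the weight. The computation actually used for published percentage
tables of this kind is ambiguous, and we make no attempt to reproduce
specific published biomass percentages; the default remains the stated
formula.

Diversity uses richness, Shannon–Wiener $H' = -\sum p_i \ln p_i$ and
Simpson $D = \sum p_i^2$ (reported in the "lower = more diverse"
orientation), computed through `vegan::diversity`. Sample completeness is
the incidence-based coverage estimator
$\hat C = 1 - \frac{Q_1}{U}\cdot\frac{(n-1)Q_1}{(n-1)Q_1 + 2Q_2}$ with
$Q_1, Q_2$ singleton/doubleton incidence frequencies, $n$ sampling units
and $U$ total incidences (the standard estimator's denominator is the
total incidence count $U$, not $n$), together with exact hypergeometric
rarefaction $E[S(m)] = \sum_i \left(1 - \binom{n - Q_i}{m} / \binom{n}{m}
\right)$, verified against exhaustive subset enumeration. Prey can be
regrouped along a three-tier hierarchy (species, group, category, e.g.
brown accentor → perching birds → birds); grouping conserves totals and
commutes with FOO.

# Guild statistics

**Similarity and ordination.** Jaccard similarity is computed on prey
presence sets at species level with "Undetermined" excluded (both choices
configurable; percentages and counts give identical sets). Dissimilarities
$1 - J$ are ordinated by classical PCoA (`stats::cmdscale`); axes with
negative eigenvalues are dropped with a warning.

**Niche overlap null model.** Pianka's index
$O = \sum p_i q_i / \sqrt{\sum p_i^2 \sum q_i^2}$ on FOO vectors is
scale-invariant; the guild value is the mean over unordered pairs. The null
model is the RA3 randomization (the conventional default for niche-overlap
tests): each species' utilization row is independently permuted across
resource columns, preserving niche breadth while scrambling resource
identity. With 999 iterations the upper-tail probability is
$p = (1 + \#\{\text{sim} \ge \text{obs}\})/(N+1)$, bounded below by
$1/1000$. Under rows that are independently and exchangeably generated
(symmetric Dirichlet-multinomial), the observed statistic is exchangeable
with its shuffles, so $p$ is discrete-uniform and the test rejects at
$\alpha = 0.05$ at the nominal rate — the calibration experiment in the
acceptance suite (500 independent matrices) checks exactly this.

**Seasonal tests.** The Friedman statistic uses within-block midranks with
the tie-corrected form
$\chi^2 = (k-1)\sum_j (R_j - b(k+1)/2)^2 / (A - C)$, defined as 0 under
complete ties, with $\chi^2_{k-1}$ p-values or exhaustive within-block
permutation (`exact = TRUE`, feasible at $(k!)^b$ small). When testing one
predator across months, blocks are prey taxa and treatments are seasons.
The Wilcoxon signed-rank test drops zero differences (classical
convention, not Pratt), midranks ties, and uses the tie-corrected normal
approximation without continuity correction by default, with exact $2^n$
sign enumeration available; both conventions are switchable. Published
test statistics of this kind depend on unstated input vectors (e.g.
whether the Undetermined category entered), so they are validated against
enumeration oracles, not against printed values.

# The synthetic guild generator

`default_scenario()` encodes the study conditions the pipeline is
validated under: 4 predators (two of them also prey, enabling intraguild
events) and 12 prey taxa on 100 bp references with all pairwise divergences
$\ge 5\%$ (rejection sampling on position-wise identity — best-local-window
identity would be meaninglessly high for any two sequences sharing a short
word, so the constraint is global). Per scat: the host is drawn from the
guild composition; the prey count is zero-truncated Poisson($\lambda =
0.8$) capped at 3 (mean $\approx 1.45$ prey/scat, matching observed means
near 1.4); reads per scat are log-normal (meanlog $\log 200$, sdlog 0.4 — a
post-filtering depth at which host calls are comfortable but the lower tail
still exercises the undetermined path); 85% of reads come from the host,
the rest split equally across prey; substitution errors are iid at 0.005
per base (indel errors are rare at amplicon scale and the mapper handles
indels regardless; an indel-free error model keeps truth bookkeeping
exact); 1% of reads are unmappable junk; scats are degraded (very few
reads) with probability 0.05 and intraguild with probability 0.02. Diet
vectors are concentrated and small-mammal-dominated, as in observed montane
guilds (one dominant prey at 0.55–0.80 plus a short tail).

What the generator does *not* emulate — PCR amplification bias, chimeras,
primer mismatch, co-amplified environmental DNA, reference-library gaps
beyond the junk fraction — bounds what green tests mean: they demonstrate
the inferential chain is correct under the declared generative model, not
that any particular wet-lab artefact is handled.

# Problem sizes, numerical choices, limitations

The recovery experiment runs 500 scats (~100k reads) and compares the
estimated FOO per predator to the *realized* truth diet matrix (what the
generator actually emitted) under total-variation distance 0.05: at this
sample size the multinomial noise between realized diets and the
generating probability vectors alone can exceed that bound for a rich
diet, so the realized-truth comparison is the one that isolates pipeline
error. Generator-versus-probability consistency is tested separately.
Null-model calibration uses 500 matrices at 999 iterations each; exact
enumerations are kept to $n \le 8$ (Wilcoxon), $3 \times 3$ (Friedman) and
5 sampling units (rarefaction), where exhaustion is instant.

Floating-point comparisons in tie-breaks use exact integer scores
throughout the aligner, so no epsilon is needed there; rank-based
statistics compare with a $10^{-12}$ slack against enumeration. Degenerate
inputs are defined, not special-cased: empty alignments have identity
`NA`, complete-tie Friedman is 0, all-zero Wilcoxon differences are an
error, coverage with no singletons is 1 and the one-unit all-singleton
limit is 0.

Known limitations: the marker cannot separate very close congeners
(e.g. domestic dog from wolf, or argali from domestic sheep) — no attempt
is made to resolve them; cannibalism is undetectable by design (host reads
mask conspecific prey); prey age/size structure is not modelled, so
biomass rests entirely on mean adult masses; and the de novo rescue is a
clustering heuristic adequate for a single amplicon, not a general
assembler.
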