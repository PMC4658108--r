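---
title: "Profiling blood miRNAs from small RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling blood miRNAs from small RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirprofiler)
```

This vignette is the package's own account of the science behind each
stage: the models and their assumptions, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical choices a maintainer would want
written down.

## The pipeline at a glance

Blood small RNA-seq libraries are dominated by mature miRNAs (~22 nt) plus
fragments of structural RNAs and technical contaminants. The pipeline
cleans reads, collapses them to unique tags, removes everything explainable
by non-miRNA references, quantifies tags against a conserved hairpin
catalog, searches the remainder for novel hairpins, tests two-group
differential expression with an exact count statistic, and predicts 3'UTR
targets for the calls.

## Read cleaning

Four whole-read filters run in a fixed order; a read is charged to the
first one that fires, so the stats ledger partitions the input exactly:

1. **Low quality** — reject when at least 50 % of bases (inclusive
   boundary; the rule is exposed as `low_quality_fraction`) are under
   Phred 5 (`quality_floor`). Evaluated on the untrimmed read, before any
   adapter handling.
2. **Adapters** — reject 5'-adapter contaminants (adapter matches the read
   start within 1 mismatch) and reads with no 3' adapter; otherwise trim at
   the leftmost 3'-adapter occurrence. An occurrence is a full internal
   match or a terminal overlap of ≥ 6 nt of the adapter prefix, with ≤ 1
   mismatch (`adapter_min_overlap`, `adapter_max_mismatch`). These
   tolerances are this package's choice: vendors' trimmers behave this way,
   and the thresholds make every decision reproducible by hand.
3. **Poly-nucleotide** — reject inserts in which one nucleotide accounts
   for ≥ 80 % of the bases (`polyN_fraction`). "Contains poly-A/T/C/G" is
   not a precise rule; single-nucleotide content with an inclusive 80 %
   boundary is the standard vendor heuristic and gives a testable edge.
4. **Length** — reject inserts under 18 nt (`min_length`); an 18 nt insert
   survives ("less than" is strict).

Quality encoding is Phred+33 (`phred_offset` exists for legacy data).
There is deliberately **no** quality-based trimming — only whole-read
rejection — because the downstream tag arithmetic ("total number" vs
"unique number") assumes inserts are exact sequencer output after adapter
removal.

## Annotation

A small RNA can match several reference classes; to give every tag exactly
one label the categories are tried in the fixed priority
rRNA > tRNA > scRNA > snRNA > snoRNA > repeat > exon > intron. Matching is
substring containment of the tag in a reference entry (a small RNA is a
fragment of a longer ncRNA), reverse complement included because reference
strandedness varies between sources; the mismatch budget defaults to 0.
Containment rather than local alignment is a deliberate simplification: it
is deterministic, has no score thresholds to tune, and on this package's
synthetic data it is exact (recall 100 % by construction). Real references
(Rfam/GenBank exports) contain truncations and SNPs where a small mismatch
budget (`max_mismatch = 1`) is worth enabling.

Category summaries are emitted over **both** denominators — unique tags and
total reads — because the two disagree strongly whenever a few miRNAs
dominate the read mass, and published category plots are ambiguous about
which was used.

## Novel miRNA discovery

### Read stacks and window excision

Candidate tags map to the genome with at most `map_max_mismatch = 1`
substitution ("less than 1 base mismatch" in protocol prose is read as the
common 1-mismatch mapper budget; 0 is selectable). Alignments cluster into
stacks when they start within `stack_max_gap = 25` nt of the running
cluster end — wide enough that a mature, its length variants, and its star
reads (across a ≤ 15 nt loop plus the 2 nt overhang) pile into one stack.
For each stack the dominant 5' position (largest read count, ties to the
5'-most) anchors two candidate windows: mature plus 70 nt of upstream
context and mature plus 70 nt of downstream context (`excise_flank`),
clipped at genome ends — the hairpin partner arm must lie on one side or
the other. Minus-strand stacks are processed on the reverse-complemented
coordinate system so windows always read 5'→3'.

### Folding

Thermodynamic folding is replaced by weighted base-pair maximization —
maximum-weight non-crossing pairing with GC = 3, AU = 2, GU = 1 and a
minimum loop of 3 nt. The weights order pair stabilities the way nearest-
neighbour free energies do at zero resolution, and the integer objective
makes the optimum exhaustively checkable: the test suite enumerates **all**
structures of windows up to 18 nt and confirms the optimum, something no
free-energy model allows at desk scale. Tie-breaking is deterministic (the
5'-most free base pairs, preferring the outermost partner), so reruns are
bit-identical.

### The signature score

The probabilistic hairpin-read score of the established discovery tools is
replaced by a transparent additive surrogate with the same reporting
threshold (> 5 points):

* `4 ×` share of stack reads whose 5' end is within ±1 nt of the dominant
  mature 5' — Dicer cuts precisely; a diffuse 5' profile is the single
  strongest anti-miRNA signal, hence the largest weight.
* `+ 3` if ≥ 60 % of mature bases are paired — the mature must lie on a
  stem arm.
* `+ 2` if star-compatible reads exist: 5' end within ±2 nt of the
  position implied by a 2 nt 3' overhang, and at least 5 nt away from the
  mature interval so jittered mature reads cannot impersonate a star.
* `+ 1` if the hairpin loop is 3–25 nt.
* `− 4 ×` share of reads whose 5' end falls in the loop — loop-derived
  reads contradict Dicer processing.

Shares are computed over the **whole stack**, not only reads inside the
candidate window; otherwise a context window that happens to exclude the
star reads would outscore the true hairpin window. A mature with no paired
base scores −∞ and is discarded.

### The structure randomization test

Each scored candidate must beat `shuffle_count = 100` dinucleotide-
preserving shuffles: `p = (1 + #{score(shuffle) ≥ observed}) / 101`, with
the add-one keeping p in [1/101, 1]. Shuffles preserve dinucleotide counts
via the Euler-walk construction (random last-edge arborescence, then
permuted edge lists), because stacking-driven structure scores are strongly
dinucleotide-dependent. The test randomizes the **candidate precursor
subregion** — the mature arm plus every base it pairs with — rather than
the full excised window: a perfect 22 bp stem inside 70 nt of random
context is otherwise diluted until shuffles of the context can match it.
Windows under 10 nt return p = 1.

Candidates on the two strands of one hairpin (a mature tag always also
matches the star arm's reverse complement) and length variants of one
precursor produce overlapping windows; overlapping candidates are grouped
as one precursor and the best-scoring representative is kept — the "same
precursor, same miRNA" rule.

A candidate is **reported** when score > `report_score_min = 5` and
p < `shuffle_alpha = 0.05`. The global signal-to-noise ratio — reported
candidates on the real genome over one plus the mean on dinucleotide-
shuffled genomes — is reported alongside, not used as a per-candidate
filter; the shuffled-genome false-candidate count doubles as the pipeline's
true-positive proxy.

### Conserved quantification

A tag counts toward a catalog miRNA when it matches inside the precursor
with its 5' end within ±2 nt of the catalog mature 5'
(`conserved_tolerance`); all tags of one precursor aggregate into one
miRNA. The ±2 window accepts natural 5' isomiR wobble while excluding
fragments of the loop or star arm.

## Differential expression

Counts are normalized to reads per million (`NE = count/total × 10^6`).
Two preprocessing rules run **before** testing, and the result table
records which fired: exact zeros become `ne_floor_substitute = 0.01`
(keeping fold changes finite), and a miRNA is excluded when its NE is under
`ne_exclusion = 1` — in *both* libraries by default. The one-vs-both
reading is genuinely open; "both" is chosen so that a miRNA silent in one
library but strong in the other (the most interesting DE pattern) is still
tested, and `ne_exclusion_mode = "either"` exposes the stricter reading. A
zero-substituted pair remains eligible for significance; only excluded
pairs are barred.

The test is the exact two-library count statistic: conditional on the total
`x + y`, the count `y` follows `p(y|x) = (N2/N1)^y (x+y)!/(x!y!)
(1+N2/N1)^{-(x+y+1)}`, evaluated in log-gamma space (it equals a negative
binomial with size `x+1` and success probability `N1/(N1+N2)`, which the
tests use as an independent closed-form oracle — never as the
implementation). The lower tail C sums the pmf to the observed count; the
upper tail D is computed by complement for numerical convergence;
`C + D = 1 + pmf(y_obs)` exactly. The statistic applies to **raw counts**
with the library totals, not to normalized values — the only reading under
which the tails are coherent. Two-sided p is `min(1, 2·min(C, D))` (capped
doubling; sidedness is a package choice, exposed through the per-tail
columns).

Significance thresholds default to p < 0.01 and |log2FC| ≥ 1
(`de_p_threshold`, `de_lfc_threshold`). With two samples per group, every
between-group pair is tested separately and a **consensus** call requires
significance with a consistent sign in all pairs — the analogue of "up in
the young individuals" across pairwise comparisons. Under a Poisson null
the consensus construction is strongly conservative (the acceptance test
measures ~1 % per-pair rejections at nominal 1 % and essentially zero false
consensus calls in 2,000 null miRNAs).

## Target prediction

Donor-species 3'UTRs transfer to the genome when an ungapped alignment
covers ≥ `utr_min_coverage = 0.8` of the donor with ≤
`utr_max_mismatch = 2` substitutions, starting within
`utr_proximity = 1000` nt of an annotated gene 3' end ("near the gene 3'
end" is quantified here; 1 kb is the scale of mammalian UTR annotation
slack). The transferred sequence is taken from the **target genome**, not
the donor. Unigene-derived UTRs are accepted verbatim as a second source.

The scanner replaces a hybridization aligner with a deterministic
seed-anchored scorer: a site needs Watson–Crick complementarity at miRNA
positions 2–8 (classes 8mer — seed plus an adenosine opposite position 1 —
and 7mer), with exactly one G:U wobble tolerated (7mer-wobble), and an
ungapped full-mature score of +5 per WC pair, +1 per G:U, −4 per mismatch
reaching `target_score_min = 60` (a 22-mer maxes at 110; 60 demands roughly
three-quarters of the duplex paired). The brute-force position-by-position
oracle in the tests reproduces the scanner exactly. Pathway tallies count a
gene once per pathway, and per-miRNA deduplicated gene links are reported
separately because published target totals are ambiguous on that point.
Target-gene expression trends use group means with a 20 % relative
difference threshold (`trend_threshold`); FPKM quantification itself is
upstream of this package and consumed as a table.

## The synthetic-data generator

`build_truth()` plants into a 10 kb random genome, largest features first,
with 40 nt of clearance (wider than the stack-clustering gap, so two
features can never merge into one stack): 6 gene intervals, 16 non-miRNA
loci (two per category, each with four fixed read start sites so the
annotation stage sees true per-category stacks), and 10 hairpin precursors
— a mature arm (20–23 nt, mode 22, echoing the blood small-RNA length
profile), an 8–15 nt loop, and the arm's exact reverse complement, with the
star strand at the canonical 2 nt 3' overhang.

`simulate_library()` draws reads multinomially: 55 % miRNA signal (8 % of
each precursor's mass as star reads), 25 % background from the planted
loci, and 20 % contaminants (5 % low-quality, 5 % missing 3' adapter, 3 %
poly-N, 4 % short-insert, 3 % 5'-adapter), each class constructed so that
exactly its filter fires — contaminant inserts are re-drawn until they
cannot trip another rule, which is what makes the label-vs-fate agreement
test exact. miRNA reads get ±1 nt 5' jitter (15 %/70 %/15 %) and ±1 nt 3'
length variation; qualities are Q40 except the planted low-quality class —
the simplest model that exercises the quality filter. Planted fold changes
multiply a precursor's proportion in young libraries; proportions then
renormalize within the fixed signal compartment, so an 8-fold planted
change yields a measured log2FC slightly under 3 (the compositional squeeze
every fixed-depth experiment has). Tests therefore plant fold changes on
low-abundance precursors, where the squeeze stays within the delta-method
bound.

What the generator does **not** emulate: sequencing errors (an optional
uniform substitution rate is out of scope by design), PCR duplicates,
ligation bias, isomiR 3' tailing, multi-locus miRNA families, and genomes
with repeats. Passing tests on this data therefore demonstrate the
*correctness of the decision rules and statistics*, not robustness to
real-library noise; parameters facing real data (mismatch budgets, adapter
tolerances) are exactly the ones exposed in the configuration.

Problem sizes used by the shipped tests and the acceptance script — a
10 kb genome, 10 precursors, libraries of 10^5 reads, 100 shuffles, 2,000
null miRNAs, 3 shuffled-genome permutations — are the package's default
study conditions; they keep every stage's behaviour measurable while the
whole suite runs in about a minute.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; strand is `+`/`-`.
* The Nussinov DP and traceback are integer-exact; ties prefer pairing the
  5'-most base with its outermost partner.
* `ac_pmf`/`ac_tails` work in log-gamma space; tails are plain sums (O(y)),
  fine for desk-scale counts, and D is computed by complement so deep upper
  tails do not require summing to infinity.
* Homopolymer windows shuffle to themselves → structure p = 1; windows
  < 10 nt are untestable → p = 1; windows < 40 nt are not folded.
* Empty inserts after trimming fall to the length filter, not an error.
* The dinucleotide shuffle retries the last-edge draw up to 1,000 times;
  sequences whose dinucleotide graph admits no arborescence (effectively
  impossible over {A,C,G,T} at these lengths) error out loudly.
* `preprocess_pair` statuses: `excluded_low_NE` bars significance;
  `zero_substituted` documents the 0.01 substitution but the pair is still
  tested — a miRNA absent in one library is a legitimate, indeed the
  loudest, differential signal.

## Known limitations

* The signature score is a surrogate, calibrated only in the sense that its
  threshold separates planted hairpins from shuffled-genome noise; its
  points are not posterior odds.
* Base-pair maximization ignores stacking energetics; hairpins whose
  biological fold depends on G:U-rich stems score relatively lower.
* The exact count statistic models sequencing as Poisson sampling; with
  biological replicates a dispersion-modelling framework is the right tool,
  and the consensus-across-pairs rule is this package's stand-in for
  replication.
* UTR transfer is ungapped; indel-diverged UTRs fail the coverage rule
  rather than aligning around the gap.
* Single-chromosome genomes are the primary path; multi-chromosome input
  is accepted by the mapper but the discovery driver processes one sequence
  at a time.
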