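---
title: "Methods: models, parameters and design choices in ntbsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ntbsmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ntbsmap` implements the analysis path from tiling-array ChIP signal to a
spatial classification of internal telomerase-subunit binding sites (NTBS),
together with a synthetic-data generator that provides every input with a
known planted truth. This vignette is the package's own account of the
models behind each stage, the parameters that matter, and the design
decisions taken where the procedure left genuine freedom.

## Coordinates and containers

All genomic intervals are `GRanges` (1-based, closed) internally; BED files
are converted at the reader/writer boundary (`read_bed()`, `write_bed()`),
which confines the 0-based half-open convention to disk. Tiling-array probe
tracks are plain data frames mirroring their on-disk table (`chrom`,
`start`, `end` in BED coordinates, `log2_ratio`, `replicate`). Contact maps
are a small S3 container (`contact_matrix`) holding a dense symmetric
matrix, the bin table, a mask of empty bins and the balancing state.

## Peak calling

Windows of `window_bp` (default 500) tile each chromosome at `step_bp`
(default 125); these defaults approximate a 200–1000 bp sheared-chromatin
fragment size, since the sliding-window scheme itself does not fix them.
A window's score is the mean log2 IP/input ratio of all probes overlapping
it. The background model is the classical mirrored-Gaussian null for
one-sided enrichment signal: windows with negative scores are assumed to be
pure noise, so the noise sd is estimated from the negative tail mirrored
about zero, `sd0 = sqrt(mean(s^2 | s < 0))`, which is consistent for
symmetric noise (checked to within 5% in the tests). One-sided Gaussian
p-values are Bonferroni-corrected over the number of scored windows — the
conservative correction that matches the published sliding-window tool's
default — and windows passing `alpha` (0.05) are merged when they overlap
or abut; a merged peak carries the smallest adjusted p among its windows.

If *no* window scores negative the null is inestimable and `call_peaks()`
stops with an error rather than silently substituting a fallback.

Replicate consensus retains a merged region iff peaks from at least
`min_support` (default 3) distinct replicates intersect it by >= 1 bp; a
fixed-fraction reciprocal-overlap rule would be stricter, but >= 1 bp is the
simplest rule consistent with "present in at least 3 of 5 replicates", and
the consensus regions are unions of peaks so near-identical calls merge
anyway. Both discovery paths are provided: per-replicate calling followed by
consensus (the reported site set) and calling on the median-standardized
track; the tests exercise both.

Telomere subtraction removes whole peaks intersecting the terminal windows
by >= 1 bp rather than trimming them: a binding site straddling the boundary
of the telomeric annotation cannot be confidently called internal. The
window width is genuinely undetermined by the procedure being reproduced;
the 15 kb default covers telomeric repeats plus the subtelomeric X/Y'
elements of *S. cerevisiae* and is exposed as a parameter everywhere.

## Permutation statistics

`shuffle_intervals()` relocates each interval uniformly within its own
chromosome, preserving the length multiset exactly, avoiding an optional
exclusion set, and forbidding self-overlap (round-based rejection sampling
with bounded retries). Keeping shuffles on the original chromosome is the
conservative null that preserves chromosomal composition. Empirical
p-values use the add-one rule `(1 + #{null >= obs}) / (1 + n_iter)`, so p
is never zero and its floor is `1/(n_iter + 1)`; resolving p < 1e-4 needs
n_iter >= 9999, which is what the acceptance script uses for the
feature-overlap test. Overlap is counted query-wise (>= 1 bp), matching
fractions quoted as "k of n sites".

## Hi-C contact maps

In-silico digestion cuts at the first base of every `GATC` (DpnII's blunt
cut). Pair classification: different fragments (any chromosomes) are valid
products; same-fragment pairs with convergent (inward) strands are
unligated fragments (`non_ligation`); divergent or equal strands are
self-circles (`self_ligation`). Equal-strand same-fragment pairs are lumped
into `self_ligation` and reported in the census rather than given a
separate class.

Binning assigns each read an aligned span of `read_len` bp starting at its
5' position on its strand, and splits the pair's unit mass across bin pairs
in proportion to the base overlap of the two spans; total matrix mass
therefore equals the valid-pair count exactly (checked to 1e-6 relative
error at 1e5 pairs and exact in the tests). The stored matrix is fully
symmetric with the diagonal not doubled. Bin size defaults to 10 kb and is
a parameter.

Balancing uses the symmetric Sinkhorn–Knopp variant — one scaling vector,
updated by the inverse square root of the current row sums — which
preserves symmetry to machine precision and converges to unit marginals on
the support. Bins with zero raw marginal are masked out, left zero, and
excluded from every downstream score (a masked query returns `NA`, never
0). Defaults: tol 1e-8 on the maximum marginal deviation, 1000 iterations;
non-convergence warns and flags the result instead of failing silently.
Duplicate-pair removal is not performed by default (the procedure being
reproduced does not state it); exact-coordinate deduplication would be a
one-line filter on the pair table.

## Telomere proximity

Sites map to the bin containing their midpoint (boundary midpoints go
downstream). Per site, `tel_score` is the **max** balanced contact with the
two telomere bins of the site's *own* chromosome — the literal reading of
"one of the two telomeres" — and an `all_telomeres` switch scores against
all 2·n_chrom telomere bins instead. Telomere bins are the single terminal
bin at each chromosome end (`k_tel` generalizes this). `ntbs_score` is the
mean contact with the bins of all other sites, self-bin excluded, missing
entries dropped; sites sharing a bin are collapsed to one bin for scoring
but reported individually. Classification is strict (`tel_score >
ntbs_score`), so exact ties — e.g. on a constant matrix — classify as
site-proximal, and the two summary fractions always add to 1 over scored
sites. Classification is invariant to global rescaling of the matrix.

The randomization test compares per-site `tel_score`s against the pooled
scores of shuffled control sets with a one-sided two-sample Wilcoxon
rank-sum test. The control shuffles must obey the same placement
constraints as the site set (in the synthetic study: outside the telomere
window plus one bin, see below); mismatched constraints bias the rank test
in either direction.

## qPCR and healing quantification

Amplification efficiency defaults to 2 (perfect doubling) and is
configurable per primer pair; fold enrichment is
`E^(Ct_input − Ct_ip)` at the target over the same quantity at the control
locus, per biological replicate. The test against the control is the
two-tailed, two-sample Student's t (equal variances) on the per-replicate
folds versus the control's folds (identically 1); a Welch flag is provided.
SEM is `sd/sqrt(n)` with the n−1 sample sd. Only biological-replicate
statistics are computed; technical-replicate averaging within plates, if
any, is assumed done upstream. Healing frequency is the exact rational
`100 · resistant / total` per construct.

## The synthetic-data generator

The generator's defaults are the study conditions used by the tests and the
acceptance script: 16 chromosomes × 200 kb, background GC 0.38, 60 planted
800-bp TG-biased sites at GC 0.52 (G carries 85% of the GC and T 85% of the
AT), five replicate probe tracks at 250-bp spacing with 5σ peaks and
per-replicate detection probability 0.9, 2·10⁶ Hi-C read pairs of 75 bp,
and a planted telomere-proximal fraction f = 0.14 (the scaled-down analogue
of 137 of 978 sites). One master seed fans out deterministically to
per-stage child streams, so a config reproduces its outputs byte for byte.

The Hi-C ground truth is a symmetric weight matrix over 10-kb bins built
in layers:

1. **Distance decay**: intra-chromosomal weight `s^(−α)` with α = 1
   (generic polymer decay) at bin separation s; the self-bin diagonal is
   set to twice the one-bin contact.
2. **Trans floor**: a uniform inter-chromosomal weight of 0.01 relative to
   the one-bin cis contact, giving a realistic ~30% trans-pair share.
3. **Rabl telomere cluster**: telomere-bin × telomere-bin weights × β
   (default 3) and telomere-bin × internal-bin weights × 0.04. The
   depletion term reflects telomere sequestration at the nuclear periphery
   and is essential: with decay alone, every internal locus contacts its
   nearest telomere bin more strongly than it contacts a set of mostly
   trans-chromosomal partner bins, and no site could ever classify as
   site-proximal.
4. **Site compartment**: NTBS-bin × NTBS-bin weights × 100 — the mutual
   spatial affinity of the binding sites that makes site-proximal the
   majority class, i.e. the structure the classifier is meant to detect.
   The matrix is then Sinkhorn-balanced so every locus keeps a unit
   contact budget (boosting a row's partners cannot create coverage out of
   nothing).
5. **Set-wide telomere affinity**: every NTBS bin's contact with the two
   telomere bins of its chromosome is set to 2.5× the *baseline* (step-3)
   balanced value. Pegging the elevation to the pre-compartment baseline
   matters: expressed as a plain multiplier it would be cancelled by the
   balancing in step 4, and the whole-set proximity signal that the
   Wilcoxon randomization test detects would vanish.
6. **Planted truth**: a random `ceiling(f · n)` subset of sites has its
   cis-telomere contacts *set* to the map's mean one-bin-neighbour contact
   (parameter `planted_tel_level = 1`) — telomere-level contact — making
   exactly those sites telomere-proximal by construction.

Pairs are drawn from the upper triangle of this map, positions uniform
within bins with uniform strands, which puts >95% of pairs on distinct
restriction fragments so they survive classification as valid products.

Two placement rules make the planted truth unambiguous at bin resolution:
sites occupy **distinct bins** (otherwise a non-planted site sharing a
planted site's bin inherits its label), and sites keep **one bin of
clearance** from the telomere windows, because proportional read binning
bleeds a little near-diagonal mass across bin boundaries and would
otherwise systematically inflate the telomere contact of a site whose bin
abuts a telomere bin. With these rules, the classifier recovers the
planted fraction exactly at the default depth across f ∈ {0, 0.14, 0.5, 1}.

The *null world* used to check the calibration of the randomization test
sets β = 1 and both site-specific affinities to 1 with f = 0 — no spatial
structure attached to sites at all — under which its p-values are uniform.
With the site compartment present but f = 0, the set-wide telomere
affinity is real structure and the test correctly rejects; calibration is
a statement about the no-structure null, not about f alone.

What the generator does *not* emulate: sequencing error, PCR duplicates,
mappability and GC coverage bias (the balancing step therefore corrects
only sampling noise here), diploid homolog ambiguity, replicate-specific
array artifacts beyond i.i.d. Gaussian noise, and any sequence-dependence
of breakage or ligation. Passing tests demonstrate that the
implementations have the stated operating characteristics on data with the
assumed structure — not that real chromatin obeys this model.

## Problem sizes and numerical choices

The unit tests run on 4 × 100 kb genomes with 8 planted sites and 10³–10⁵
pairs; the acceptance suite uses the full default study (16 × 200 kb, 60
sites, 2·10⁶ pairs) for the proximity recovery grid, 100 noise seeds for
the false-peak bound (tested against the 99.9% Poisson quantile of the
Bonferroni expectation), 500 simulations for permutation-test calibration,
and >= 1000 random instances per brute-force oracle comparison (fragment
assignment, overlap counting, consensus, balancing). These sizes were
chosen so each property is measured with sampling error well inside its
asserted band. Ties in `findInterval`-based assignments follow half-open
interval semantics throughout (a position on a cut or boundary belongs to
the downstream fragment/bin). All stochastic code paths take explicit
seeds and restore RNG state (`withr`), so test results are reproducible.

## Known limitations

* The peak caller assumes a shared probe grid across replicates and
  one-sided (enrichment) signal; depletion analysis would need a two-sided
  null.
* Contact matrices are dense; genomes beyond ~10⁴ bins would need a sparse
  backend.
* `shuffle_intervals()` uses rejection sampling; it will give up (with an
  error, never silently) on near-saturated chromosomes where few valid
  placements exist.
* The proximity classifier works at bin resolution: sites closer than one
  bin to each other or to a telomere are not resolvable, which is why the
  generator enforces the placement rules above; real data carries no such
  guarantee and per-site calls near bin boundaries should be read with
  that caveat.
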