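---
title: "Pan-genome construction, rarefaction and ANI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome construction, rarefaction and ANI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind **panstrep**, the parameters
that matter, the numerical choices, and what the bundled simulator does
and does not emulate. It is the package's own account of its methods; all
empirical statements here are recomputed by the test suite or by
`scripts/acceptance.R`.

```{r setup, eval = FALSE}
library(panstrep)
```

## The accretion algorithm and the BCR homology rule

The pan-genome is built by iterative gene-pool accretion. The reference
strain's genes become the initial pool, one singleton cluster each — the
algorithm never clusters within the reference, so duplicated reference
genes remain separate pool entries. Every gene of every subsequent
strain, in order, is aligned against the pool; it joins the best-scoring
cluster it is homologous to, or founds a new cluster (and pool entry)
otherwise. Because the pool only ever grows and representatives are the
founding genes, the procedure is cheap and insensitive to how clusters
accumulate members; the alternative — updating representatives towards a
centroid — would change the algorithm and was deliberately not done.

Homology between a query and a pool gene is decided from their best
local alignment by the *BLAST coverage ratio* (BCR) rule. With
`BCR_q = L_aln(q)/L_q` and `BCR_s = L_aln(s)/L_s`, a pair is rejected
only when **both** ratios fall below `bcr_min` or identity falls below
`identity_min`. The one-sided acceptance matters: a short gene fully
contained in a longer one still counts as homologous even though the
longer side's coverage is poor. Identity is counted over aligned columns
with gap columns excluded (the BLAST reporting convention), and
alignments shorter than `min_len` residues are discarded up front.

### Thresholds

The decision thresholds are deliberately ordinary, mid-range values, all
configurable and echoed into every result object:

| parameter | default | unit | rationale |
|---|---|---|---|
| `bcr_min` | 0.5 | fraction | half-coverage, the common ortholog-calling midpoint |
| `identity_min` | 70 (nt) / 50 (aa) | % | conventional nucleotide/protein homology floors |
| `min_len` | 30 | residues | drops micro-HSPs that carry no signal |

No result in the package depends on these specific defaults — the tests
exercise rule *semantics* (one-sided acceptance, monotonicity in
`bcr_min`) and ground-truth recovery under conditions where families are
separated by construction.

### Alignment and the k-mer prefilter

Alignment is Smith–Waterman with affine gaps (match/mismatch +2/−3 and
gap open/extend 5/2 for nucleotides; BLOSUM62 with 5/2 for proteins).
When several local alignments tie, the single best-scoring one defines
the covered spans; score ties between candidate clusters are broken
towards the lexicographically smallest founder id, making output
deterministic.

Aligning every gene against every pool entry is quadratic and wasteful,
so two sound shortcuts are applied:

* **Exact-duplicate fast path.** A query byte-identical to a pool
  sequence joins that sequence's cluster directly. Identity attains the
  maximal possible alignment score, so this is consistent with
  best-score assignment.
* **Shared k-mer prefilter** (k = 9 nucleotide, 4 protein). A pool
  entry is a candidate only if it shares at least
  `max(2, ceiling(2·L_q·L_s/|Σ|^k))` distinct k-mers with the query. The
  threshold scales with the *chance* shared-k-mer rate of unrelated
  sequences (≈ `L_q·L_s/|Σ|^k`), while genuinely homologous pairs at or
  above `identity_min` share roughly `identity^k · L` k-mers — an order
  of magnitude more at every length the package accepts. The contract
  that the prefilter never removes a pair the full alignment would
  accept is verified in the tests by exhaustive no-prefilter comparison
  runs on diverged fixtures.

Searching against cluster founders only (rather than all members) is the
default: it is cheaper, order-stable, and matches the pool-of-founders
reading of the accretion scheme; `search = "all"` is available when
member-level sensitivity matters.

### Degenerate cases

With a single strain, every cluster is simultaneously "in all strains"
and "in exactly one"; panstrep reports them as strain-specific and
documents that core counts are meaningful only for `N ≥ 2`. Empty gene
sets and duplicate gene ids are rejected with validation errors.

## Rarefaction curves and convergence models

For each sampled strain ordering, pan and core sizes are computed for
every prefix; all `N!` orderings are enumerated when `n_perm ≥ N!`
(sampling is seeded otherwise, default `n_perm = min(N!, 200)` — at nine
strains, 200 sampled orderings already give stable medians). Per-`n`
**medians** are fitted rather than means: medians are standard for
dilution curves and robust to ordering outliers (configurable by fitting
any other summary externally; the raw per-permutation curve is returned).

Two models are fitted:

* **Core decay** `C(n) = A·exp(−n/τ) + Ω`, by Levenberg–Marquardt
  nonlinear least squares. Start values come from the curve itself
  (`A ≈ range`, `τ ≈ span/3`, `Ω ≈ min`), with box constraints
  `A, Ω ≥ 0`, `τ > 0`. A constant curve short-circuits to the exact
  degenerate fit `A = 0, Ω = mean`. A perfect fit can exhaust the
  iteration cap while polishing a ~0 residual, so convergence is also
  granted when the RMSE is below `1e-6` of the data range; true
  optimiser failure yields `converged = FALSE`, never an exception.
* **Pan growth** `P(n) = K·n^γ`, by linear least squares on the log-log
  scale. The pan-genome is *open* when `γ > 0` with its 95% CI excluding
  zero; an absolute floor of `1e-6` on γ keeps numerically flat curves
  (slope ~1e-16 with vanishing s.e.) from being called open. The
  exponential decay form for the core follows the classic usage in
  pan-genome studies; the power law for pan growth is this package's
  documented choice of openness model, flagged as such in output
  metadata.

## ANI

ANI follows the ANIb conventions: 1,020-bp consecutive fragments (a
final remainder is kept only if ≥100 bp), fragment-vs-genome search with
`blastn` (`-task blastn -reward 1 -penalty -1 -xdrop_gap_final 150
-dust no -evalue 1e-15`, both strands), best hit per fragment, filters of
30% identity and 70% fragment coverage, mean identity of surviving
fragments, and reciprocal averaging of the two directions (which makes
`ani_mean` exactly symmetric). All parameters are fields of
`ani_params()` and are echoed in results. Delegating the fragment search
to BLAST+ is both the field's convention for ANIb and the only practical
option at genome scale; an in-R Smith–Waterman of 1-kb fragments against
megabase genomes would be quadratic in the wrong place. When no fragment
passes the filters the ANI is reported as `NA` with a zero used-fragment
count — distant or highly fragmented inputs are a result, not an error.

Under the simulator's substitution model (each site independently
replaced by a different base with probability *r*), the expected
fragment identity against an unmutated copy is exactly `100·(1 − r)`,
which gives a closed-form oracle: the tests hold ANI to within three
binomial standard errors of that expectation across a divergence ladder,
and to exactly 100 on self and reverse-complement input.

## Presence/absence phylogeny

Strain profiles over gene families give Jaccard distances,
`d = 1 − |F_i∩F_j|/|F_i∪F_j|`, resolved by classical neighbor joining.
On additive matrices NJ reproduces the generating tree exactly (verified
against recomputed path-length matrices); on non-additive input it can
produce negative branch lengths, which are clamped to zero with a
warning and a `clamped` flag so Newick output stays valid. Trees are
unrooted; the two-taxon case is resolved in closed form (one edge, the
distance split equally). This distance surrogate replaces
likelihood-based gene-family trees by design: it is transparent,
dependency-light, and adequate for topology-level comparison, but it is
not an ML phylogeny and no bootstrap support is computed. An ANI matrix
can be transformed to distances as `d = (100 − ANI)/100` and fed to the
same NJ step.

## What the simulator emulates — and what it does not

`simulate_pangenome()` generates the structure that pan-genome methods
consume: `n_core` families present in all strains, dispensable families
present in a chosen number of strains, strain-specific singletons, and
optional paralogs (extra members of an existing family, labelled with
the same family id — accordingly, recovery on paralog-bearing
simulations is asserted at cluster level, not gene level). Family
members derive from a uniform-random ancestor by i.i.d. per-site
substitution at rate `divergence`; two members of the same family then
match at an expected `(1−r)² + r²/3` of sites, which the tests use as a
binomial oracle. Ancestor lengths are uniform on `gene_length_range`,
default 150–3000 bp — bracketing typical bacterial CDS lengths, whose
genome-wide averages sit around 900 bp. Ancestors are uniform over the
alphabet because no compositional claim is being tested; a GC-bias knob
exists but defaults to off.

Deliberately absent: indels, rearrangements, horizontal transfer, codon
structure, and length variation within a family. Passing tests on these
simulations therefore demonstrates that the algorithms are correct under
their stated model — family recovery, curve shapes, ANI expectations —
not that the thresholds are tuned for any particular real genus, where
gene fission/fusion and mosaic genes blur the BCR decision in ways the
simulator does not produce.

Simulated genomes (`sim_genomes()`) concatenate each strain's genes with
uniform-random spacers of 100–400 bp and record GFF3-style 1-based
closed coordinates, which exercises the genome-stats and ANI readers on
files with known answers.

## Genome feature statistics

`feature_summary()` merges overlapping gene intervals before length
accounting. Union semantics is the only convention under which gene and
intergenic lengths partition the genome exactly — the identity
`gene_total + intergenic = genome` is asserted, and duplicated intervals
are provably harmless. Percentages are rounded to two decimals (repeat
fraction to four, matching the precision such tables print), the average
gene length to the nearest bp using the *pre-merge* gene count. GC
content excludes ambiguity codes from numerator and denominator — a
documented, conservative convention — and errors on empty or
all-ambiguous input rather than returning 0. With zero genes the average
gene length is reported as `NA`, never 0. Published
genome-characteristics tables sometimes contain rows that are not
arithmetically reconstructible from the other rows (for example regional
GC values inconsistent with the whole-genome GC); panstrep computes
regional GC from sequence when sequence is available and otherwise
leaves such fields `NA`.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale by choice:
the ground-truth recovery condition is nine strains with 50 core, 20
dispensable (spread over presence levels 2–8) and 5 specific families
per strain (~590 genes); alignment-oracle checks use exhaustive
substring enumeration on sequences up to 12 bp; ANI fixtures are 20–100
kb genomes; fit-recovery uses 100 seeded replicates. Every stochastic
step takes an explicit seed, simulation output is byte-reproducible, and
the pipeline manifest records a config hash so reruns can be verified
identical.
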