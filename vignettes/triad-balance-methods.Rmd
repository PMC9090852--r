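---
title: "Methods: quantifying homoeolog triad expression balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying homoeolog triad expression balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadbalance)
```

## The problem

Hexaploid wheat arose from two hybridisations that reunited three diploid
genomes (A, B, D) in one nucleus, so a typical nuclear gene is a
*homoeolog triad*: three near-identical copies, one per subgenome, whose
transcripts can be told apart by subgenome-diagnostic sequence variation.
Genome-wide surveys have found most triads expressed in a balanced way,
with single-subgenome suppression more common than single-subgenome
dominance among the asymmetric remainder. For any particular gene set —
here, the Rubiscosome, the nuclear-encoded machinery of Rubisco biogenesis
and regulation, packaged as the worked registry — the practical questions
are: how is each gene's expression split across its triad, is that split
tissue-dependent, and does it move under stress? `triadbalance` answers
these from two inputs a practitioner actually has: a registry mapping gene
names to subgenome-resolved locus identifiers, and a tpm expression matrix
with sample metadata.

## Identifier parsing and the registry

Wheat RefSeq identifiers are structured
(`TraesCS7A02G341000`: species, accession, chromosome 7 subgenome A,
assembly version, locus number; a decimal suffix denotes a transcript
isoform). `parse_gene_id()` decomposes them and `format_gene_id()` is its
exact inverse; the locus number stays a string so leading zeros round-trip.
The assembly-version segment is treated as an opaque two-digit string: the
nomenclature gives no grounds for interpreting it further, and the parser
should not fail on a future assembly that changes it.

Two registry rules are deliberate:

* **Unplaced loci require explicit overrides.** A locus on the unassigned
  chromosome (`TraesCSU...`) has no parseable subgenome. Assigning it one
  is a scientific claim — in the packaged registry, the unplaced Raf2
  locus is assigned to D, a call supported by its high protein identity
  with the placed A and B copies — so the loader refuses unknown-subgenome
  loci unless an override names them, and flags every overridden entry.
  Silent guessing would be invisible in downstream tables.
* **Incomplete triads warn but load.** Gene loss and assembly gaps are
  real; a registry with a two-subgenome gene is usable for the genes it
  does cover, but the user is told.

Duplicated locus IDs are an error (a registry is a partition), and an
unknown gene name passed to `count_loci()` is an error rather than a zero,
because the zero would silently absorb typos.

## Aggregation

For samples passing a context filter, the per-locus mean tpm is the plain
arithmetic mean over those samples, pooled across studies with equal
per-sample weight. Pooling is the default because it is the most literal
reading of "mean over the selected samples"; a study-stratified mode
(`stratify_by_study = TRUE`) that averages per-study means is provided for
users who want studies weighted equally regardless of how many samples
each contributed. Per-subgenome totals sum the gene's loci within each
subgenome using the registry's *effective* subgenome, so multi-copy genes
(RbcS: 9/8/8 copies) and overridden loci aggregate correctly. Fractions
are each total over the grand total; log2 total expression has **no
pseudocount** — a zero-total triad has undefined fractions, and such
(gene, context) pairs are reported in a `dropped` attribute instead of
being assigned a made-up position on the simplex.

Missing (locus, sample) cells are an error for a matrix declared dense
(the default): in a dense table, absence means the registry and the
expression matrix disagree, which the user must see. A matrix declared
sparse (`dense = FALSE, fill = 0`) fills missing cells with an explicit
value instead.

## Balance classification

The seven archetypes are fixed points on the simplex: balanced
(1/3, 1/3, 1/3), X-dominant (1 at X), X-suppressed (0 at X, 1/2 at the
others). Assignment is nearest-centroid under Euclidean distance in the
raw 3-D fraction space; this is equivalent up to a constant factor to
Euclidean distance in ternary-plot coordinates, so the geometric picture
and the classification agree. Ties are broken by the fixed centroid order
(balanced; dominants A, B, D; suppresseds A, B, D), making the call
deterministic.

No published numeric boundary defines "generally considered balanced", so
rather than inventing one, the classifier reports a **boundary set**:
every centroid whose distance exceeds the minimum by at most ε (default
0.05 in fraction-space distance, chosen as roughly the scale of rounding
in published percentage splits; always configurable). The set is monotone
in ε and always contains the category. A triple like (0.19, 0.16, 0.65)
then reports B-suppressed as nearest, with balanced, A-suppressed and
D-dominant all within ε = 0.06 — the honest description of a point on a
multi-category boundary.

Ternary coordinates use vertices A = (0, 0), B = (1, 0),
D = (1/2, √3/2) — A bottom-left, B bottom-right, D top — via
x = f_B + f_D/2, y = f_D·√3/2. The orientation is fixed and documented
here; the package emits coordinates and leaves plotting to the user.

## Condition comparison

`compare_contexts()` is defined only where both totals are positive
(fractions are undefined otherwise; the caller sees an error, not an
arbitrary number). "Changed" means a category transition at the chosen ε.
This is an operationalisation: a qualitative changed/unchanged split needs
*some* fixed rule, and a category transition is the one consistent with
the classifier, while the boundary sets of both sides are carried along so
a transition between adjacent regions can be recognised as marginal.
Fold changes are ratios of triad totals after subgenome summation, so they
are invariant to any common rescaling of both contexts and independent of
the fraction split. Genes present on only one side are listed in
`missing_from` / `missing_to`, never dropped.

## Sequence identity

Alignment is global Needleman–Wunsch with affine gaps (a length-L gap
costs `gap_open + L * gap_extend`), computed by `Biostrings`; defaults are
BLOSUM62 with open −10 / extend −1 for protein and match 2 / mismatch −3 /
open −5 / extend −2 for nucleotide. The defaults matter less than their
documentation: published identity figures from GUI aligners rarely state
parameters, so comparability is approximate by nature and every parameter
here is overridable. Percent identity divides identical columns by **all**
alignment columns, gaps included in the denominator — one fixed,
documented convention. Multi-sequence summaries are the mean over pairwise
global alignments (matching the "pairwise identity" of a three-homoeolog
comparison), not a multiple-alignment column statistic. The test suite
checks the aligner against two independent oracles: exhaustive enumeration
of every global alignment for short pairs, and a separately written
iterative affine dynamic program for the complete sweep of binary-alphabet
sequences up to length 6.

One caveat the user should know: a constraint like "pairwise identities
100 %, 98 %, 96 % among three sequences" is geometrically impossible
(identity 100 % forces two sequences equal, which forces their identities
to any third sequence equal), so three-way fixtures in the tests use
consistent triples such as 98/96/94.

## The simulator: what it emulates and what it does not

`simulate_dataset()` draws per-(locus, sample) tpm as

```
tpm = base_tpm * true_fraction / copies_in_subgenome * stress_multiplier * noise
```

with multiplicative log-normal noise of mean 1 parameterised by its
coefficient of variation (CV). The log-normal is the natural minimal model
for a positive, heteroscedastic unit like tpm; mean 1 makes recovery
unbiased by construction, which the Monte-Carlo tests confirm rather than
assume. Within-subgenome copies split their subgenome's share equally —
downstream aggregation sums them, so the split is irrelevant to results
but must be defined for the generator to be well specified. Stress effects
multiply a named homoeolog in a named context, emulating condition-specific
induction of one subgenome copy. Homoeolog sequence trios are built from
one random base sequence with each substituted position diverging in
exactly one subgenome; the requested pairwise counts (AB, AD, BD) are
solved for per-subgenome private substitution counts and rejected when
inconsistent.

Default study conditions used in the validation tests and acceptance
script: noise CV 0.2 and 10 samples per context for stochastic recovery
(500 balanced triads; the observed mean-fraction bias is well under 0.02),
noise 0 for exact end-to-end recovery over a seven-archetype truth set,
and a 380-residue protein trio with A/D identical and 4 private B
substitutions for the sequence mirror. These sizes keep the full suite to
minutes on a single core while leaving the Monte-Carlo standard errors an
order of magnitude below the tolerances being checked.

What the simulator does **not** model: study-specific batch effects,
between-sample library-composition artefacts in tpm, read-level sampling
noise, correlated noise among homoeologs, or indel divergence between
homoeolog sequences. Passing the synthetic validation therefore shows the
pipeline's arithmetic and classification are correct under the stated
generative model — it does not show that real cross-study pooled tpm is
free of batch structure. For real data the study-stratified mean and the
boundary sets are the provided mitigations.

A single integer seed drives all randomness, and the generator
save-restores the caller's RNG state, so simulations are reproducible and
side-effect free.

## Numerical choices and degenerate inputs

* Simplex membership is checked with tolerance 1e-6 on the sum; published
  rounded percentages (e.g. a 17/53/28 split summing to 0.98) must be
  renormalised by the caller — the package refuses to guess.
* Fraction sums reproduce 1 within 1e-9; centroid distances match
  brute-force recomputation within 1e-12 (both are tested, not assumed).
* Zero-length sequences, empty sample selections, empty context overlaps,
  all-zero triads, and off-simplex fractions are all errors with specific
  messages, not silent empties.
* An empty registry table loads as an empty registry (a valid, useful
  degenerate case for pipelines that build registries programmatically).

## Known limitations

* Balance categories derive purely from nearest-centroid geometry; the
  package does not implement significance-based category schemes that test
  deviation from 1:1:1 against replicate variance.
* No differential-expression statistics: condition comparison describes
  shifts, it does not test them.
* Identity figures are not guaranteed bit-identical to those from other
  aligners' conventions (different gap handling or denominators); the
  convention here is fixed and documented instead.
* tpm is consumed as provided; computing tpm from reads, and discovering
  homoeologs in the first place, are out of scope — the registry is an
  input.
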