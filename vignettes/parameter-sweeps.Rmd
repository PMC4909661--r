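---
title: "Selecting alignment parameters by reference-based sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting alignment parameters by reference-based sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnsweep)
```

## The problem

Progressive multiple sequence aligners expose three parameters that dominate
their accuracy: the gap open penalty (GOP), the gap extension penalty (GEP)
and the substitution matrix (SM). Most users run the defaults, but defaults
are a compromise across all input regimes; on a specific family of proteins
— very low identity, a diverged orphan, long internal insertions — a
different (SM, GOP, GEP) combination is often measurably better. When a
curated reference alignment is available for a set of benchmark families,
the combination can simply be *measured*: align each family's sequences
under every candidate combination, score each result against the reference,
and pick the combination with the best average score.

`alnsweep` implements that measurement loop end to end: scoring, grid
construction, sweep execution over any aligner, and the aggregation that
selects the optimum per dataset.

## The sum-of-pairs score

All selection in this package is driven by the sum-of-pairs score (SPS). A
residue is identified by its row and its position in that row's ungapped
sequence — never by its letter — and two residues are *aligned* when they
occupy the same column. For a test alignment of $N$ rows and $M$ columns,
the column score is

$$S_i = \sum_{j=1}^{N} \sum_{k \ne j} p_{ijk},$$

where $p_{ijk} = 1$ exactly when the residues in rows $j$ and $k$ of column
$i$ are aligned with each other in the reference. The alignment's score is
the ratio

$$\mathrm{SPS} = \frac{\sum_{i=1}^{M} S_i}{\sum_{i=1}^{M_r} S_{ri}},$$

with the denominator the same sum taken over the $M_r$ columns of the
reference itself, so $\mathrm{SPS} \in [0, 1]$ and the reference scores 1
against itself. The double sum counts ordered pairs; the ratio is invariant
under halving both sums to unordered pairs, which is what the
implementation does (`sps(..., ordered = TRUE)` reports the doubled counts,
and the test suite asserts the equivalence). The column score
(CS, `cs()`) — the fraction of scored reference columns whose exact residue
content reappears as a single test column — is computed alongside as a
stricter secondary metric.

Two conventions vary across the literature and are explicit options here:

* **Core masks.** Curated references often annotate reliably aligned "core
  blocks" and are scored only on them. When a reference carries a mask,
  both numerator and denominator are restricted to masked columns by
  default (`use_core_mask = FALSE` scores every column). Nothing in the
  package asserts which convention a given published table used; both are
  available.
* **Sparse columns.** Reference columns with fewer than two residues
  contribute $S_{ri} = 0$ naturally and so never affect SPS. For CS,
  residue-less columns are never scored (they define no content), and
  `skip_single_residue_columns = TRUE` additionally drops single-residue
  columns from the CS denominator.

Scoring is case-insensitive because benchmark files use letter case to mark
core regions; masking is handled explicitly instead.

## The sweep and the selection rule

`grid_spec()` generates combinations as exact decimal multiples of the
steps (default GOP 0.1–3.0 by 0.1, GEP 0.03–1.50 by 0.03, six matrices:
BLOSUM30/45/62/80, PAM100/200), so grid values serialize losslessly and act
as stable keys across checkpoints. `run_sweep()` evaluates the full
cases × combinations cross product, records failures as FAILED cells rather
than aborting, checkpoints finished cells to TSV, and resumes interrupted
sweeps without recomputation.

Selection is a three-stage reduction, each stage a plain argmax:

1. `mean_sps()` — **MEAN_SPS**: the unweighted mean SPS over the cases of a
   dataset at one combination (each reference counts once; FAILED cells are
   excluded, or scored 0 under `fail_as_zero = TRUE`).
2. `max_mean_sps()` — **MAX_MEAN_SPS**: per matrix, the maximum MEAN_SPS
   over the GOP × GEP grid.
3. `select_optimal()` — the matrix with the largest MAX_MEAN_SPS is the
   dataset's optimal matrix, and its argmax (GOP, GEP) the optimal
   penalties.

Ties are broken deterministically: smallest GOP, then smallest GEP within a
matrix, then matrix listing order (BLOSUM30, 45, 62, 80, PAM100, PAM200)
across matrices — preferring weaker penalties and the conventional listing.
Means are stored at full precision and only rounded to 4 decimals for
reports, so rounding can never flip a rank. The test suite checks the whole
reduction against a one-pass brute-force argmax on random tables, including
invariance to record order.

`compare_parameter_sets()` reports named combinations side by side — e.g.
the progressive-aligner default (BLOSUM62, GOP 1.53, GEP 0.123, the
defaults popularized by MAFFT) against the measured optimum — either by
re-aligning every case (`mode = "rerun"`) or by quoting an existing sweep
table (`mode = "quote"`); the output labels which mode produced it. When
the default combination lies on the swept grid, the measured optimum
dominates it by construction; the interesting quantity is the margin.

## Aligners

The sweep is aligner-agnostic. Two routes are provided:

* **Built-in progressive aligner.** A deliberately minimal but correct
  progressive aligner: Gotoh three-state affine-gap alignment (a gap of
  length $L$ costs $\mathrm{GOP} + \mathrm{GEP}\cdot(L-1)$, terminal gaps
  penalized like internal ones), profile–profile merges along a UPGMA guide
  tree over 3-mer distances, with profile columns scored by the expected
  substitution score under the column residue frequencies (gaps contribute
  only through the gap states). Every tie in the dynamic program and the
  guide tree is broken by a fixed rule (match before gap-in-second before
  gap-in-first; lexicographic id pairs), so identical inputs yield
  byte-identical output. Pairwise optimality is tested against exhaustive
  enumeration of all alignments of short sequences. It exists so sweeps run
  end to end with zero external dependencies; it is *not* an emulation of
  any production aligner — no FFT segmenting, no iterative refinement, no
  consistency objective.
* **External aligners.** `aligner_spec()` describes any command-line tool
  by a whitespace-tokenized template with `{input}`, `{output}`, `{gop}`,
  `{gep}` and `{matrix_flag}` placeholders; rendering substitutes tokens
  verbatim and never passes user data through a shell. Packaged templates
  for MAFFT (L-INS-i-style) and CLUSTALW ship in
  `inst/extdata/aligners/aligners.yaml`. Two caveats are inherent and
  documented there: MAFFT's `--ep` is a score offset whose semantics differ
  subtly from a textbook GEP (values are passed verbatim), and MAFFT
  exposes no Dayhoff PAM tables, so PAM100/PAM200 map to `--jtt 100/200`
  (JTT-PAM) unless the user overrides the mapping. Which MAFFT strategy to
  sweep is a template choice, not code. Every external result is verified
  to ungap back to the input sequences; tool failures become FAILED sweep
  cells, while an output that *parses* but loses or alters sequences is
  raised as an integrity error.

## Substitution matrices

The six swept matrices are the canonical NCBI integer tables, shipped as
plain-text files in NCBI whitespace format (`read_matrix_file()` loads
user-supplied tables in the same format). PAM100/PAM200 are the classical
Dayhoff-derived tables, not MAFFT's JTT variants — the flag mapping above
is where that divergence is handled. Note that published copies of the
same matrix can differ: BLOSUM80 is distributed by NCBI in 1/3-bit units
while some packages ship a half-bit variant, and ambiguity-code entries
(B/Z/X) differ between derivations; the tests pin the packaged tables to
the NCBI versions via digests of independently sourced copies. Residues
outside a matrix's alphabet (e.g. U, O, J) are scored as X, logged once.

## The synthetic benchmark generator

`generate_family()` produces families with a *known true alignment* so the
entire loop is testable without curated data or external binaries. An
ancestor drawn from background amino-acid frequencies evolves down a
balanced or caterpillar tree; each edge carries an equal share of the
root-to-leaf divergence. Substitutions hit each site with probability
$1 - e^{-t}$ and replace the residue by a draw from a BLOSUM62-compatible
exchange distribution ($P(b \mid a) \propto p_b \, 2^{S_{ab}/2}$); indels
arrive as a Poisson number of events per branch with geometric lengths,
insertions creating new true columns occupied only by the inserting
lineage's descendants and deletions leaving gaps (deletions are capped so
no lineage shrinks below 10 residues). The emitted reference *is* the site
homology: residues descending from one ancestral or inserted site share a
column, every row ungaps to its leaf sequence, and everything is
reproducible from the seed.

The six packaged presets (`benchmark_presets()`, RV11-like … RV50-like)
loosely mirror the strata of curated benchmark collections — equidistant
low identity, 20–40 % identity, family plus diverged orphan, divergent
subfamilies, long terminal extensions, long internal insertions. The
identity-critical divergences were fixed once by simulation before being
packaged: divergence 1.80 puts the RV11-like stratum near 13 % mean
pairwise identity (below its < 20 % ceiling) and divergence 0.85 puts
RV12-like at ≈ 0.31 with all replicates inside the 20–40 % band. What this
generator does **not** emulate is equally important: no rate heterogeneity
across sites, no codon structure, no domain architecture, no alignment
ambiguity in the reference (its truth is exact by construction), and the
orphan/extension strata are approximated only through tree shape and indel
length. Green tests on synthetic data therefore demonstrate that the
machinery is correct — scores exact, optima genuinely optimal, pipeline
deterministic — not that any particular parameter value transfers to real
protein families.

`perturb_alignment()` complements the generator for scorer tests: it
re-gaps a chosen fraction of residues into private columns, giving test
alignments of known, monotonically decreasing quality.

## Numerical and design choices

* Grid values are built by integer multiplication and decimal rounding —
  never by accumulating floating-point steps — so `1.2` is always `1.2`.
* Pair counting is internally unordered; the ordered double-sum form is
  exposed as an option and proven equivalent in tests.
* The affine convention charges GOP for the first gap position and GEP per
  additional position, terminal gaps included; a direct switch between the
  two gap states opens a new gap. Conventions differ between tools, which
  is one reason external-aligner penalty values are passed verbatim rather
  than "translated".
* Degenerate inputs fail loudly and specifically: ragged records name the
  offending row, references with no co-occupied column raise "defines no
  aligned pairs", empty grids and unknown matrix names are configuration
  errors.
* Problem sizes in the shipped workflow (`analysis/`) and tests are
  desk-scale by design — families of 4–8 sequences around 70–120 residues,
  grids of tens of combinations — chosen so the full loop, including the
  exhaustive oracles, runs in minutes on one core while still exercising
  every code path at full cross-product scale.

## Workflow

The `analysis/` scripts run the whole study shape on the synthetic
benchmark: `01_simulate.R` writes the benchmark and its identity summary,
`02_sweep.R` sweeps a 60-combination grid over all 18 cases (checkpointed),
`03_aggregate.R` produces the MEAN_SPS / MAX_MEAN_SPS / optimal-parameter
tables, and `04_compare.R` quotes measured-optimal against default
parameters per dataset. `scripts/acceptance.R` condenses the same loop into
one seeded, from-scratch run that writes its headline numbers as JSON.

## Known limitations

The built-in aligner's absolute SPS on hard strata is modest (it is a
minimal progressive method); the package measures and ranks parameter
combinations, it does not claim state-of-the-art alignment. CS conventions
vary across published benchmarks, so CS values are comparable within a
sweep but not necessarily to external reports. XML-based benchmark
annotations and nucleotide alphabets are out of scope; core masks are read
from plain-text column ranges.
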