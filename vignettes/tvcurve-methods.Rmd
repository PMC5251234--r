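---
title: "Comparing RNA secondary structures with TV-curves and multi-scale wavelet similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing RNA secondary structures with TV-curves and multi-scale wavelet similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvcurve)
```

## The problem

Alignment-based RNA structure comparison (tree edit distances, Sankoff-style
simultaneous fold-and-align) is accurate but expensive, typically cubic in
sequence length. This package takes the alignment-free route: an RNA and its
secondary structure are turned into a numerical curve, and two RNAs are
compared by correlating the wavelet decompositions of their curves. The
pairwise score then powers two applications: scanning all single-point
mutants of an RNA for structural impact, and building UPGMA trees over RNA
sets.

## The TV-curve encoding

A structured RNA is first written in a *characteristic representation* over
eight symbols: `A, C, G, U` for unpaired bases and the primed `A', C', G',
U'` for bases taking part in a base pair. Each symbol maps to a triple of
vertical steps in $\{-1,+1\}$:

| symbol | steps | symbol | steps |
|---|---|---|---|
| A  | $(+1,+1,+1)$ | A' | $(-1,-1,+1)$ |
| U  | $(+1,-1,+1)$ | U' | $(-1,+1,+1)$ |
| G  | $(+1,-1,-1)$ | G' | $(+1,+1,-1)$ |
| C  | $(-1,+1,-1)$ | C' | $(-1,-1,-1)$ |

Concatenating the triples of an $N$-nt RNA gives $3N$ steps; their
cumulative sums from the origin are the *triple-vector curve* (TV-curve),
$3N+1$ points whose $x$ coordinate is the step index. Because the table is a
bijection over the eight sign patterns, the curve determines the sequence
*and* the pairing status of every base exactly — `decode_steps()` inverts
`tv_curve()` symbol by symbol.

A note on the table: of the $2^3 = 8$ sign patterns, seven assignments are
fixed by the method's definition, but published statements of the eighth
(C') conflict with the one-to-one claim by duplicating G's pattern. We
assign C' the unique pattern left over, $(-1,-1,-1)$, which is the only
choice consistent with bijectivity. This is surfaced in the documentation
of `tv_step_table` because it is the one place where this implementation
had to resolve an inconsistency rather than transcribe a definition.

```{r encode}
rec <- rna_record("hairpin", "GAAAC", "(...)")
cv <- tv_curve(rec)
cv$symbols
cv$points[nrow(cv$points), ]   # endpoint: x = 3N, y = sum of steps
```

## Multi-scale similarity

Two curves are compared level by level after a wavelet decomposition:

1. Extract the signal of each curve. The default is the cumulative ordinate
   sequence $y_1,\dots,y_{3N}$ (the curve itself); the raw $\pm 1$ step
   signal is available via `tvc_config(signal = "steps")`. Which of the two
   the original method decomposes is not documented; we default to the
   cumulative curve because the decomposition of the curve is what the
   method's description names, and we keep the alternative as a knob.
2. Resample both signals to the smallest power of two at least as long as
   the longer one, by linear interpolation on a uniform grid with endpoints
   preserved. No length-equalization scheme is documented for comparing
   RNAs of unequal length; linear resampling to a shared dyadic length was
   chosen because it lets the $L$-level orthonormal pyramid run exactly,
   with no boundary padding.
3. Decompose each signal to $L$ levels (default $L = 4$, the method's
   stated default). The wavelet family is configurable; the default is
   Haar, the natural match for step signals and exact in dyadic
   arithmetic. A Daubechies-4 transform with periodic boundaries is also
   provided (`wavelet = "d4"`).
4. Correlate per level: $\rho_0$ is the Pearson correlation of the two
   approximation vectors $a_L$, and $\rho_j$ that of the detail vectors
   $d_j$, $j = 1..L$. Correlations are taken per level, not on concatenated
   coefficients, so coarse (global) and fine (local) structure contribute
   separately.
5. The similarity is the weighted sum $s = \sum_{j=0}^{L} w_j \rho_j$ with
   $\sum w_j = 1$. The weights are undocumented in the method's public
   description; we default to uniform $w_j = 1/(L+1)$ and expose them
   (`--weights` on the CLI, `weights =` in `tvc_config()`). Any positive
   rescaling of the weight vector gives the same score.

Degenerate levels need a convention: a coefficient vector of length one or
with zero variance has no Pearson correlation. We score such a level 1 if
both vectors are constant and equal, else 0. This matters for inputs like
homopolymers, whose curves are straight lines.

The structural distance is $d = 1 - s \in [0, 2]$; identical records are at
distance 0.

```{r similarity}
a <- tv_curve(rna_record("a", "GGGGAAAACCCC", "((((....))))"))
b <- tv_curve(rna_record("b", "GGGGACAACCCC", "((((....))))"))
multiscale_similarity(a, a)
multiscale_similarity(a, b)
```

## Folding backends

Records may carry their own dot-bracket structures (the extended FASTA
dialect, including RNAfold-style energy annotations, which are stripped).
When a structure is missing it is predicted:

* `fold_backend("external")` shells out to ViennaRNA's `RNAfold` and uses
  its minimum-free-energy structure, with the tool's default parameters.
* `fold_backend("nussinov")` is the built-in fallback: maximum base pairing
  over $\{AU, UA, GC, CG, GU, UG\}$ with hairpin loops of at least
  `min_loop` (default 3) unpaired bases, solved by the standard $O(N^3)$
  dynamic program. The traceback tie-break is pinned — prefer leaving the
  left end unpaired, else pair it with its smallest admissible partner — so
  results are bit-reproducible everywhere.

The fallback is a combinatorial model, not a thermodynamic one; it will
happily pair random sequences more densely than a free-energy model would.
That is acceptable for its role here: a deterministic, self-contained
structure source for tests and synthetic data, with the external adapter
restoring thermodynamic folding when the binary is present. The test suite
and the reproduction script never require the external tool.

## Mutation scanning

For an $N$-nt record each position admits exactly three substitutions,
giving $3N$ mutants. Every mutant is re-folded with the same backend —
mutants never inherit the wild-type structure, since the point is to detect
structural change — and scored by $1 - s$ against the wild type. The result
contains the ranked mutant table, the *deleteriousness profile* (the
per-position maximum over the three substitutions), a histogram of all $3N$
distances (default 20 uniform bins over $[0, \max d]$), and the single
maximal mutant. Ties for the maximum are broken by lowest position, then
substitution in `A < C < G < U` order, so reports are reproducible. When a
file holds several records, only the first is scanned, with a notice.

```{r scan}
scan <- scan_mutations(rna_record("hp", "GGGGAAAACCCC"))
scan$maximal
```

## Distance matrices and UPGMA trees

`pairwise_distance_matrix()` needs at least three records, folds what must
be folded, computes each of the $n(n-1)/2$ distances once and mirrors them.
`upgma()` is classical unweighted pair-group averaging: merge the closest
pair of clusters, replace their distances by the size-weighted mean
(equivalently the plain mean of all cross-cluster leaf distances), repeat.
Equal minima are broken by the lexicographically smallest pair of cluster
labels (a cluster is labelled by its smallest descendant leaf), again for
reproducibility. The returned object is `hclust`-compatible, so
`stats::cophenetic()` and `stats::cutree()` work directly; on an
ultrametric input the cophenetic distances reproduce the input exactly.
`to_newick()` renders the ultrametric tree (branch length = parent height
minus child height, heights being half the merge distances) with children
ordered by smallest descendant label.

## Synthetic data: what it does and does not emulate

`generate_synthetic()` plants sequence families: per family a random
ancestor is drawn and folded with the fallback backend, and each member is
an independent per-site mutant of the ancestor (substitution probability
`mutation_rate`, every hit site switching to one of the other three bases)
that is then re-folded. Defaults — 4 families, 20 members, 60 nt, rate
0.05 — are the package's standing study conditions for tree-recovery
checks: at 60 nt and 5% divergence families are structurally coherent but
not trivially identical, a desk-scale stand-in for curated family sets. The
generator emulates neither indels, nor compensatory (covariation) double
substitutions, nor thermodynamic folding, so a perfect recovery score here
shows the pipeline separates substitution-divergent structure families —
it does not certify performance on curated natural families.

With those defaults a 4-way cut of the UPGMA tree (at the three deepest
internal edges, i.e. `cutree(tree, 4)`) recovers the planted families; the
reproduction script `scripts/acceptance.R` measures the adjusted Rand index
of that cut, along with the other quantities reported there.

## Numerical choices and limitations

* All curve arithmetic is integer until resampling; resampling and the
  pyramid are double precision. The Haar pyramid inverts its input to
  better than $10^{-9}$ (measured at $10^{-15}$ in the tests).
* Signals shorter than $2^L$ after resampling reduce $L$ to
  $\lfloor \log_2 \text{len} \rfloor$ with a warning; the weights are
  renormalised over the surviving levels. With the 10-nt input minimum the
  default configuration never triggers this.
* Problem sizes in the tests (pairs up to 64 nt, 80-record trees,
  length-20 scans) keep the whole suite under a minute while exercising
  every contract at full depth; they are stated here as the package's own
  verification design.
* Only nested (pseudoknot-free) structures in single-bracket dot-bracket
  are supported; multi-bracket dialects are rejected explicitly.
* Multiple-point mutants and suboptimal-structure ensembles are out of
  scope.
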