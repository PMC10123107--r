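---
title: "Fitness functions for RNA design: models, search and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness functions for RNA design: models, search and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

RNA design (inverse folding) asks for a sequence $p \in \{A,U,G,C\}^n$
whose predicted secondary structure equals a given target $t$.  Under a
thermodynamic model $m(p,s)$ the prediction is
$\mathrm{Fold}(m,p) = \arg\min_{s \in S(p)} m(p,s)$, where $S(p)$ is the
set of properly nested structures realizable on $p$ with canonical
pairs (AU, GC and the GU wobble).  Pseudoknots and base triples are out
of scope.  This package treats a design as **correct only when the
target is the unique, untied MFE structure** of the designed sequence:
a tie means the model cannot distinguish the target from a competitor,
which is a poor starting point for a molecule that must fold reliably.
Co-optimality is detected at the backend's energy resolution (integer
0.01 kcal/mol units in both backends), so tie detection is exact rather
than a floating-point accident.

Search algorithms need a scalar **fitness function** to climb.  The
package implements the four families that dominate the literature, all
oriented so that higher is better:

* **Probability**: $P(t \mid p) = e^{-m(p,t)/RT}/Z(p)$, the Boltzmann
  probability of the target in the equilibrium ensemble.
* **Free energy**: $-\Delta G(p,t)$, the negated free energy of the
  target on the candidate.
* **GC-controlled free energy**:
  $-\Delta G - 10\,\frac{e^{\max(0,\hat g-g)}-1}{e-1}\,|\Delta G|$,
  where $\hat g$ is the candidate's GC fraction and $g$ the target GC
  fraction (default 0.5).  The penalty is zero while $\hat g \le g$ and
  grows exponentially above it, counteracting the strong GC bias of
  plain free-energy minimization.  The $|\Delta G|$ factor is read as
  the free energy of the *target* structure on the candidate — the same
  quantity as the first term — which is the only self-consistent
  reading; it is the `be_energy()` call in `fitness_batch()`, so a
  different convention is a one-line change.  Note the degenerate case
  $\Delta G = 0$: the whole expression collapses to 0 regardless of GC
  content.  We keep that behaviour.
* **Ensemble defect**: $1 - D(p,t)/n$ with
  $D(p,t) = \sum_{s \in S(p)} P(s \mid p)\, d(s,t)$, the expected
  number of nucleotides whose pairing status differs from the target,
  where $d$ counts positions whose partner differs (unpaired positions
  partner with themselves).  $D$ is computed from base-pair
  probabilities as
  $n - \sum_{(i,j)\in t} 2P_{ij} - \sum_{i\ \mathrm{unpaired}} (1 - \sum_j P_{ij})$,
  never by enumeration; the enumeration form is what the tests check it
  against.
* **Structure distance**: similarity between the target and
  $\mathrm{Fold}(p)$ under base-pair distance (BPD), structural Hamming
  distance (HD) or the Matthews correlation of base pairs (INF), with
  three policies for co-optimal ties: `arbitrary` (the backend's single
  returned structure), `average` (mean distance over all co-optimals)
  and `minimum` (best case).  BPD/HD fitness is $n - d$; INF fitness is
  the correlation itself.

INF here is the Matthews correlation coefficient over all
$\binom{n}{2}$ candidate pairs.  Part of the literature instead uses
$\sqrt{\mathrm{PPV}\cdot\mathrm{sensitivity}}$; the two differ little
on secondary structures, and the MCC reading is the one we adopt.  When
the MCC denominator is zero (for instance both structures empty) the
score is defined as 0 with a warning, which keeps distance fitness
finite on degenerate targets.

## The search algorithm

`adaptive_random_walk()` is a deliberately plain hill climber, chosen
because it works unchanged with every fitness family and so compares
them fairly.  One walk:

1. Seed with `seed_sequence()`: unpaired positions i.i.d. with
   $P(G)=P(C)=g_s/2$; each target pair jointly set to GC/CG with
   probability $g_s$, AU/UA otherwise (orientation uniform).  Pairs are
   therefore canonical from step zero.  Wobble pairs are reachable by
   mutation but not used in seeds, which keeps the seed's GC content
   exactly $g_s$ in expectation.
2. For each of `steps` (default 1000) iterations, pick a mutation unit
   uniformly from {unpaired positions} ∪ {target pairs}; change an
   unpaired base to one of the other 3 bases, or a pair to one of the
   other 5 canonical ordered pairs (GU/UG included).  Accept iff the
   fitness **strictly** increases — no epsilon, no plateau drift, no
   restarts, no early exit.
3. After the budget, assess correctness once with the unique-MFE
   criterion.

Strict improvement makes "current" and "best-so-far" the same
sequence, so the distinction is moot.

Acceptance is exposed as a policy (`accept_equal`).  The default is
the literal strict rule, and it is what all reported numbers use.  The
choice is consequential only for plateau-rich fitness functions: the
structure distances take few integer values, so most mutations leave
the fitness unchanged and a strict walk stalls on plateaus (typically
finishing 2–6 Hamming units from the target with a unique wrong MFE),
while probability and ensemble defect are smooth enough that exact
ties essentially never occur.  With `accept_equal = TRUE` the walk
drifts neutrally across plateaus and the structure-distance families
solve far more 40nt puzzles (in our experiments, close to every one),
which suggests implementations reporting strong structure-distance
results allow such drift; the smooth families are unaffected either
way.  We keep strict acceptance as the default because it is the
stated rule of the algorithm, and read the structure-distance rows of
our own benchmarks as strict-acceptance numbers.  Each walk's randomness is drawn
up front from its own seed with a fixed consumption pattern (the
mutation replacement is encoded as an offset uniform on 1..15, which
maps uniformly to both the 3 base alternatives and the 5 pair
alternatives), so results are bit-reproducible, identical whether the
walk runs alone or batched, and a benchmark's per-puzzle seeds do not
shift when fitness functions are added or removed.

## Backends

All thermodynamics go through a backend interface (`be_energy`,
`be_prob`, `be_defect`, `be_coopt`, `be_subopt`, ...).

`vienna_backend()` adapts the ViennaRNA package (default parameters,
37 °C) through its Python bindings, kept alive in a worker process
speaking JSON lines over named pipes; a 1000-step walk then costs one
pipe round trip per step rather than one process launch.  Suboptimal
enumeration is ViennaRNA's implementation of Wuchty's algorithm; the
co-optimal set is its zero-window case.  The installed ViennaRNA
version is recorded in run metadata, since energy-parameter drift
between releases shifts benchmark numbers slightly.

`reference_backend()` is a self-contained energy model used to make
every downstream computation verifiable by brute force: canonical
pairs, minimum hairpin size 3, integer centi-kcal energies consisting
of stacking terms by pair class (strong/strong −3.30, strong/weak
−2.10, weak/weak −1.10, any wobble −0.50 kcal/mol) plus constant loop
penalties (hairpin +4.50, bulge +3.80, internal +2.30, multiloop
+4.40) and a free exterior.  The parameters are chosen so that
minimum-energy structures are non-trivial from about a dozen
nucleotides (two strong stacks beat one hairpin penalty; two weak ones
do not).  It is *not* the nearest-neighbor model and is never used for
headline numbers; it exists because at $n \le 12$ its entire structure
ensemble can be enumerated in R, giving independent oracles for the
C++ implementations of folding, Wuchty-style threshold-pruned
suboptimal traceback, the inside partition function and outside
base-pair probabilities.  The test suite checks, over hundreds of
random sequences, that $\sum_s P(s|p) = 1$ and that the
ensemble defect matches $\sum_s P(s|p) d(s,t)$ to $10^{-9}$, that
suboptimal enumeration equals brute-force thresholding exactly, and
that tie detection agrees with exhaustive minimization.  RT is
0.61633 kcal/mol (310.15 K) in both backends.

## Synthetic puzzles

`generate_puzzles()` reproduces the benchmark's data distribution:
uniform random sequences; all suboptimal structures within
$T$ kcal/mol of the MFE; one target drawn uniformly per sequence;
duplicate targets rejected dataset-wide.  On a duplicate we redraw a
*fresh sequence* rather than re-sampling the same suboptimal list,
preserving the per-sequence uniform choice.  The study conditions are
40nt with $T = 1.0$ and 80/120nt with $T = 5.0$ kcal/mol.  Sampling
from the suboptimal window rather than from MFE structures (too easy)
or uniformly over all structures (unsolvably hard) produces targets
that discriminate between fitness functions.  A per-sequence
enumeration cap (default $10^6$) bounds memory at 120nt/$T=5$;
sequences over the cap are skipped with a warning.

What the generator emulates — and what it does not: targets are
thermodynamically plausible for *some* random sequence, with the
motif mix summarized by `dataset_stats()` (at desk scale we measure a
mean paired fraction of about 44% at 40nt rising to the mid-50s at
120nt, in line with the window construction).  It does not emulate
evolved RNA: no covariation, no conserved motifs, no length/GC
distributions of natural families.  Benchmarks on these puzzles
therefore say how well a fitness function guides search toward
*model-consistent* targets; the separate rank analysis
(`rank_true_structure()`) is the bridge toward natural
sequence/structure pairs, and `read_ct()` accepts curated collections
(not bundled) for it.

## Benchmarks and problem sizes

`run_benchmark()` runs one 1000-step walk per (puzzle, fitness
function), batching all walks of one function in lockstep so each step
is a single backend request.  The summary mirrors the usual reporting:
solve count, solve rate, mean final GC fraction, and the number of
puzzles only that function solved ("unique solver", always relative
to the panel actually run).

One partition-function evaluation costs roughly 1 ms at 40nt, 6 ms at
80nt and 14 ms at 120nt on one CPU, and a walk needs 1001 of them, so
full-paper scale (1600 puzzles × 13 functions × 3 lengths) is a
cluster-sized computation.  The package's desk-scale defaults — a few
hundred 40nt walks, a few dozen at 80nt, 20–30 at 120nt, as wired into
`scripts/acceptance.R` and the acceptance tests — keep a complete
reproduction within tens of minutes.  The corresponding binomial
standard error is about 0.01 at 40nt but 0.07–0.10 for the 80/120nt
solve rates; the long-length numbers should be read with that noise
floor in mind.

## Ranking true structures

For a sequence with a known structure, `rank_true_structure()` grows a
suboptimal window from 0 in 0.2 kcal/mol increments until at least
`min_structures` structures are enumerated (200000 at paper scale;
desk-scale runs use a few thousand) or the window passes 10 kcal/mol,
scores every structure as a hypothetical design target, and reports
the true structure's competition rank (ties share the best rank — the
conservative choice for the true structure, and stable under
permutation of the list).  A true structure absent from the list is
replaced by its closest enumerated structure by base-pair distance;
if even that differs by more than 5% of the length (typically a pair
the model cannot form), the RNA is excluded.  Free energy is not
offered here: with the sequence fixed, it orders structures exactly as
probability does, which the tests assert.

## Numerical and design choices

* Energies cross the backend boundary in kcal/mol; tie detection
  happens on the backend's integer representation.
* Structures are 1-based integer pair maps with `pm[i] == i` for
  unpaired positions (the natural R indexing); dot-bracket strings are
  the interchange form, CT the import form for natural data.
* Fitness comparisons use strict `>` with no tolerance: probabilities
  and defects are smooth, and an epsilon would change walk behaviour
  unpredictably.
* `run_benchmark()` derives per-puzzle seeds by position from the
  master seed, so records are reproducible row by row.
* Probability fitness is evaluated as $e^{(G - E)/RT}$ from the
  ensemble free energy rather than via enumerated sums, and the
  ViennaRNA worker rescales its partition function around the target's
  energy to avoid overflow on long sequences.

## Known limitations

* Nested structures only; no pseudoknots, triples or quadruplexes.
* The ViennaRNA adapter needs its Python bindings at run time; the
  reference model is pure C++/R and always available, but it is a toy
  model whose absolute energies mean nothing outside this package.
* Desk-scale solve rates at 80/120nt carry ±0.1 binomial noise, and
  the installed ViennaRNA version's parameters shift rates slightly
  relative to other releases.
* The rank analysis is only as good as the suboptimal window: for
  long or very stable RNAs, 200000 structures may cover a tiny slice
  of the ensemble.

## A worked miniature

```{r}
library(rnafitness)
backend <- vienna_backend()
ps <- generate_puzzles(30, 40, 1.0, backend, rng_seed = 101)
dataset_stats(ps)$mean_paired_fraction
specs <- lapply(c("prob", "fe", "ed"), parse_fitness_spec)
bm <- run_benchmark(ps, specs, backend, steps = 1000, master_seed = 202)
bm$summary
```

At this size the run takes about a minute: probability and ensemble
defect solve nearly every puzzle at ~50% GC, while free energy solves
a small fraction and pushes GC toward 0.75 — the pattern the analysis
scripts reproduce at larger scale.
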