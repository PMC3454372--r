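---
title: "A geometric mixture model of bacterial ORF length statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A geometric mixture model of bacterial ORF length statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfstat)
```

## The model

Double-stranded DNA read in triplets supports six reading frames: `+1`,
`+2`, `+3` on one strand and `-1`, `-2`, `-3` on its reverse complement.
`orfstat` fixes the convention that `+1` is the frame of the annotated
genes at a locus and `-1` is the antiparallel *in-register* frame (the one
whose codons are exactly the reverse complements of the `+1` codons).  An
open reading frame (ORF) is the longest run of in-frame triplets from a
start codon (`ATG`, `GTG`, `TTG`, `CTG` by default) to the next in-frame
stop codon — one ORF per stop, beginning at the first start codon after
the previous in-frame stop.  Lengths are counted in codons, including the
start and excluding the untranslated stop.

The model's only fitted input is the codon usage $\pi$: the frequency of
each of the 64 codons in the concatenation of all annotated ORFs, read on
the coding strand and including each gene's terminal stop codon.  Everything
else is derived:

* **Frame +1** is modeled as independent, identically distributed (IID)
  codons drawn from $\pi$.  The stop probability per codon is
  $\rho_{+1} = \sum_{c \in \text{stops}} \pi(c)$, the start probability
  $\tau_{+1}$ the analogous sum over the start set.  Because one terminal
  stop is counted per gene, $\rho_{+1} \approx 1/(\bar L + 1)$ with
  $\bar L$ the mean annotated gene length in codons.
* **Frame −1** reads the reverse complement of each `+1` codon, so its
  codon distribution is $q(c) = \pi(\mathrm{revcomp}(c))$.  This is why,
  e.g., leucine `CTA` in `+1` puts a stop `TAG` in the antisense register.
* **Frames ±2, ±3** read triplets straddling two consecutive codons.  Over
  IID codons these readings are Markov chains with memory one on 64 states.
  For `+2` the transition law factorizes as
  $Q\big((a,b,c) \to (d,e,f)\big) = \frac{\pi(c,d,e)}{m_1(c)}\, m_1(f)$,
  where $m_1$ is the first-position marginal of $\pi$; for `+3` the
  conditioning is on the first two positions ($m_{12}$).  Frames `-2` and
  `-3` apply the same construction to $q$.  The frame's codon distribution
  is the chain's stationary law, and $\rho_i$, $\tau_i$ are its stop- and
  start-set masses.  When every codon has positive usage the chains are
  ergodic; `stationary_distribution()` solves $(Q^\top - I)d = 0$ with the
  normalization row appended (power iteration as fallback) and refuses
  reducible chains.

Within one frame, a codon position is inside an ORF or between ORFs;
entering happens on a start ($\tau_i$), leaving on a stop ($\rho_i$).  The
stationary law of this two-state chain gives the in-ORF fraction
$\alpha_i = \tau_i/(\tau_i+\rho_i)$, and dividing the in-ORF codon mass by
the mean dwell $1/\rho_i$ yields the expected ORF count

$$N_i = n_i\,\frac{\tau_i \rho_i}{\tau_i + \rho_i}, \qquad
  n_i = \lfloor n_{\mathrm{bp}}/3 \rfloor .$$

ORF lengths in frame $i$ are geometric on $\{1, 2, \dots\}$ codons, and the
genome-wide length law is the six-component mixture

$$P(L = \ell) = \sum_i w_i\,(1-\rho_i)^{\ell-1}\rho_i, \qquad
  w_i = N_i / \textstyle\sum_j N_j ,$$

with mean $\sum_i w_i/\rho_i$ — independent of the genome length.  The
probability that at least one of $N$ ORFs reaches length $\ell$,

$$S(\ell) = 1 - \big(1 - P(L \ge \ell)\big)^{N},$$

is the *survival probability*, read as a p-value against the random-genome
null; `survival_limit()` inverts it.  The expected number of annotated
genes is $N_{+1}$, optionally constrained to a minimal gene length through
the frame `+1` tail $(1-\rho_{+1})^{\ell_{\min}-1}$ (the package records
this exponent convention as `tail_exponent_offset = -1`, the exact tail of
the geometric support fixed by the scanner's minimal ORF of one codon).

## A worked pipeline

```{r example, eval = FALSE}
usage <- bacterial_usage(gc = 0.505, seed = 1)
sequence <- rcodon_simulate(usage, 3e6, seed = 2)
orfs <- find_orfs(as.character(sequence))

fp <- frame_probabilities(usage)
model <- build_model(fp, genome_bp = 3e6)
model
orf_statistics(orfs)$count      # compare with model$N
survival_limit(model, 0.01)    # codons
```

For annotated genomes, `read_genome()` (GenBank flat file, or FASTA plus a
TSV gene table) feeds `compare_genome()`, which runs gene filtering, aORF
extraction, usage estimation, the model, one Rcodon realization and both
ORF scans, and `shadow_candidates()`, which ranks non-annotated ORFs by
their per-frame survival probability.

## Parameters that matter

* `start_set`, `stop_set` (`genetic_code_config()`): codon sets; defaults
  `{ATG, GTG, TTG, CTG}` and `{TAA, TAG, TGA}`.  `mollicute_code()` drops
  `TGA` for *Mycoplasma*-like genomes; with a uniform usage this changes
  $\rho$ from $3/64$ to $2/64$ and propagates exactly through every formula.
* `genome_bp` (`build_model()`): sequence length in bp; enters only through
  $n_i$ and hence the counts $N_i$ and survival trials, never the shape of
  the length law.
* `pvalue` (`survival_limit()`, `shadow_candidates()`): significance level
  against the longest-ORF null.  No multiple-testing correction is applied —
  survival probabilities are reported per frame together with the trial
  counts $N_i$ so users can correct as they see fit.
* `seed`: one integer drives every random step (ambiguity resolution,
  Rcodon simulation) through an isolated RNG stream; identical inputs and
  seeds give identical outputs.

## What the synthetic generators emulate

`rcodon_simulate()` is the null model itself: IID codons from a usage, at
the genome's length, with frame `+1` ORFs "annotated" by definition.

`bacterial_usage()` fabricates a usage resembling an annotated bacterial
gene set at a chosen GC content: the third codon position carries most of
the GC signal and the second is AT-shifted; multiplicative log-normal
scatter (sd 0.35 on the log scale) mimics synonymous codon preference; and
the total stop-codon mass is pinned to $1/(\bar L + 1)$ with a default mean
gene length of 300 codons, the value that makes predicted gene densities
(~3 genes per 10 kb at GC 50%) match real chromosomes.  It reproduces the
qualitative behavior of real genomes — mean ORF length rising steeply with
GC, alternative-frame stop probabilities far above $\rho_{+1}$ — but not
their amino-acid composition, operon structure, strand asymmetry, or
intergenic composition.  Tests passing on these usages therefore validate
the mathematics and the scanner, and the *shape* of genome-scale behavior;
they do not certify agreement with any particular organism's annotation.

`random_usage()` (flat Dirichlet) is deliberately harsher than any genome:
its stop mass (~4.7%) is an order of magnitude above real usages.  It is
used where exactness is expected regardless of realism — the frame-shift
chains and their stationary laws, which match simulations to sampling
accuracy for *any* strictly positive usage.

## Accuracy of the average-case approximation

The per-frame counts $N_i$ and the geometric length law are exact for the
IID frames ±1 and an *average-case approximation* for the shifted frames,
whose start/stop occurrences are weakly autocorrelated through the
memory-one chain.  Measured against simulations at 3 Mb, totals agree to
well under 1% at GC ≈ 50% (mirroring the agreement reported for real
enterobacterial chromosomes), while at GC 35% — where alternative-frame
stop probabilities reach 0.12 per codon — per-frame counts can deviate by
up to ~5% and the mixture mean by ~2.5%.  This error is a property of the
model, not of the implementation: an exact computation on the joint
128-state (codon, in-ORF) chain reproduces simulated counts to within
sampling noise.  Users analyzing very AT-rich genomes should expect
per-frame expectations to be accurate to a few percent, not fractions of a
percent.

## Numerical and design choices

* Stationary laws: direct linear solve (residual < 1e-12) with power
  iteration (tol 1e-14, ≤ 1e5 iterations) as fallback; 64 states make
  exactness cheap.  Usage codons with zero mass leave some chain states
  unreachable; their rows are replaced by the frame's unconditional codon
  distribution so the matrix stays stochastic without touching the
  stationary law of the reachable class.
* Ambiguity symbols are resolved uniformly at random over their IUPAC
  substitution sets with a caller-supplied seed: this preserves expected
  base composition and is reproducible.  Genes whose span is not a
  multiple of three, or whose terminal codons were ambiguous before
  resolution, are excluded from usage estimation.
* Chromosomes are treated as linear even when flagged circular; wrap-around
  genes, `join()` locations and pseudo-genes are skipped with a warning.
  The edge effect is a handful of ORFs per genome.
* ORFs truncated by the sequence end (no stop codon) are not emitted; the
  model counts stop-terminated ORFs only.  The minimal ORF is start + stop
  (one codon).
* Relative frames are assigned to non-annotated ORFs by largest bp overlap
  with an aORF (ties: longer aORF, then lower start), with the `-2`/`-3`
  labels placed so that per-frame ORF counts line up with the chains that
  define $\rho_{-2}$, $\rho_{-3}$ — the `-2` grid sits at forward-phase
  offset 2 from a `+`-strand aORF, not offset 1.  naORFs overlapping no
  aORF are reported as unassigned and are scored with the all-frame
  mixture survival in the shadow screen.
* The 75% quantile uses the lower nearest-rank rule, the natural choice for
  integer codon lengths.
* Survival trials default to the model's expected $N$ (rounded; a
  continuous relaxation is available), matching the convention that the
  trial count is itself a model quantity rather than an observed count.

## Problem sizes used by the test suite

The suite validates the chains on 10^6-codon simulations, end-to-end
self-consistency on 3 Mb genomes (three GC levels × three seeds), survival
calibration on fifty 3 Mb realizations, and the scanner against a
brute-force enumerator on two hundred 300 bp sequences; these sizes hold
sampling error well below the tolerances they check while keeping a full
run to about a minute.

## Known limitations

* Intergenic sequence is ignored by construction (it is a small fraction of
  bacterial chromosomes); the model is not applicable to intron-bearing
  eukaryotic genomes.
* Annotation quality propagates: usages estimated from sparse or biased
  gene sets (e.g. expression subsets) change every downstream prediction —
  which is also what makes the gene-subset interface useful for studying
  codon-usage-driven artifacts in antisense frames.
* Survival probabilities treat ORFs as independent draws from the mixture;
  overlapping ORFs in different frames are not independent in reality.
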