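---
title: "Comparing PKS/NRPS gene-cluster repertoires between close bacterial strains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing PKS/NRPS gene-cluster repertoires between close bacterial strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcrep)
```

## The problem

Actinomycete genomes encode dozens of secondary-metabolite biosynthetic
gene clusters (BGCs), dominated by modular polyketide synthases (PKS) and
nonribosomal peptide synthetases (NRPS). Two strains can be almost
indistinguishable by 16S rDNA — a single nucleotide over ~1451 compared
positions — and still belong to different genomic species with largely
different BGC repertoires. This package quantifies that repertoire overlap
and connects it to genome-based species delimitation.

The packaged example is a pair of close *Streptomyces* strains: TP-A0598
(9 PKS/NRPS clusters) and *S. angustmyceticus* NBRC 3934 (13 clusters),
shipped as plain-text inventories transcribed from their published cluster
tables.

## The domain-organization grammar

Each synthase gene is described by its catalytic domain string, e.g.
`C/A(leu)/T` (one NRPS extension module: condensation, adenylation loading
leucine, thiolation) or `KS/AT/DH/ER/KR/ACP` (a fully reducing type I PKS
module). `-` separates modules, `/` separates domains, parentheses carry
A-domain (occasionally T-domain) substrate calls, and `...` marks
undetermined stretches. Parsing preserves the printed segmentation
verbatim — module boundaries are data, not inference. The canonical
serialization writes substrates as `A(leu)`; the markdown-escaped dialect
`A_(leu)_` and the spellings `KSα`, `KSa`, `KSβ (CLF)` seen in typeset
tables are accepted on input and normalized (the underscores are
typesetting artifacts, and ASCII codes keep files portable).

Module classes are a pure function of the domain set: `NRPS_EXT` (C+A+T),
`NRPS_LOAD` (A+T without C), `NRPS_NO_A` (C+T without A), `PKS_EXT`
(contains KS), `PKS_LOAD` (CoA-ligase loading), `TERMINATION_ONLY`
(TE/TD), and `FRAGMENT` for everything else (lone A or ACP genes, partial
reductive loops of truncated ORFs). Cluster types follow domain content:
dissociated KSα/KSβ(CLF) subunits make a type II PKS, a standalone
single-KS ORF a type III PKS, mixed PKS and NRPS modules a hybrid, and so
on; a declared type disagreeing with content warns rather than errors,
because typing in source tables is itself an annotation.

## Backbone prediction

The colinearity rule says the product's building-block order mirrors the
module order. The predictor walks ORFs in assembly order — table order by
default, an explicit recorded order where the table order is known not to
be the biosynthetic order (two hybrid clusters in the packaged data), or a
simple loading-first/release-last heuristic — and emits one token per
biosynthetic module:

| module | token |
|---|---|
| NRPS module, substrate called | capitalized residue (`Leu`) |
| NRPS module, substrate uncalled | `x` |
| NRPS module with MT, substrate uncalled | `mx` |
| NRPS module without A domain | `y` |
| type I PKS extension module | `pk` |

Epimerization domains never change the emitted residue. A new chain starts
when a loading module follows a TE/TD-released segment (clusters encoding
two independent assembly lines render as `"Thr-Thr-x, Arg-Pro"`). A
standalone A-domain ORF followed by a T-carrying module is fused into it
(in-trans loading), which is required to reproduce hybrid products such as
`Ala-Thr-pk`. The final chain is marked open-ended (trailing `-`) when the
last walked ORF lacks a release domain *and* the cluster is incompletely
sequenced — `mx-x-Gly-` — whereas a complete cluster simply ending without
TE/TD is reported closed. One `pk` is emitted per PKS extension module, a
convention that matters only for multi-module PKS stretches where no
printed counterexample exists. Loading PKS didomains (CoL) prime the line
but add no unit, since their starter is chemically unspecified.

Type II and type III PKS clusters are rejected by the predictor
(`bgcrep_not_an_assembly_line`): their chemistry is not colinear.

## Matching repertoires and RC

The conservation statistic is

$$RC\,(\%) = \frac{2\,C_{ab}}{A + B} \times 100,$$

with $A$, $B$ the strains' PKS/NRPS cluster counts and $C_{ab}$ the number
of conserved pairs — a Dice coefficient on cluster sets, symmetric,
bounded by [0, 100], and equal to 100 exactly when the repertoires match
one-to-one. Percentages are reported both exact and rounded half-up to
integers, the convention of the source tables (`45%`, `56%/44%`,
`38%/62%` for the packaged pair).

The conserved pairs can be supplied as an expert map (a published
"present in both genomes" call is data, and always overrides inference) or
inferred from architecture. Inference scores every same-type cluster pair
by a global alignment of module-signature sequences and solves the exact
maximum-weight one-to-one assignment over pairs scoring at least the
threshold (default 0.7), with deterministic lexicographic tie-breaking.
The aligned-module score is the Dice similarity of the two modules'
domain-kind multisets, times a substrate-agreement factor (1 when equal or
both uncalled, 0.5 when one-sided, 0.25 when both called and different),
zero across module classes; unaligned modules cost 0.25 each; the total is
normalized by the longer module count. The design constraints behind this
scoring were, in order: identical architectures must score 1; swapping one
substrate call out of four modules must land at $(3 + 0.25)/4 = 0.8125$
(substrate identity is strong evidence and its loss must be penalized
hard, else unrelated NRPS clusters of similar shape cross the threshold);
a single accessory-domain difference (DH present in one copy of an
otherwise identical module) must stay well above threshold, because real
orthologous clusters differ this way; and an extra accessory ORF must
drag a pair of short, otherwise identical type II clusters *below* 0.7,
because dissociated type II architecture is so stereotyped that two
unrelated clusters are architecturally near-identical — only the graded
Dice mismatch plus the explicit gap cost achieves the last two at once.
On the packaged pair, inference at 0.7 reproduces the expert map exactly;
the tie among architecturally identical type II candidates is resolved
lexicographically, mirroring the genomic-context evidence an expert would
use but architecture alone cannot see.

The assignment itself is solved exactly (connected-component decomposition
of the thresholded bipartite graph, then dynamic programming over column
bitmasks per component), and is verified in the tests against brute-force
permutation search on random instances. Components wider than 22 columns
are refused rather than approximated; realistic within-type components
are far smaller.

## 16S identity and species boundaries

Pairwise 16S similarity is reported as `matches/compared positions`
(`1450/1451 = 99.93%` style). Columns with a gap or `N` in either sequence
are excluded from the denominator, so it counts genuinely compared
positions; `U` reads as `T`. Unaligned input is globally aligned first
(match +2, mismatch −1, gap open −5, gap extend −2 — ordinary rDNA
parameters; for reproducing printed fractions the prealigned path is
authoritative, since published alignment parameters are rarely stated).
Percentages round half-up at the second decimal.

Species calls use the standard genomic criteria: same species iff
dDDH ≥ 70% (inclusive), falling back to ANI ≥ 95% when dDDH is absent,
`undetermined` when both are. dDDH and ANI are consumed as inputs — they
come from external genome-to-genome computations and are deliberately out
of scope. The concordance analysis is ordinary least squares over
complete-case strain-pair records (simplest defensible missing-data
policy); $r^2$ is direction-invariant, so which variable is plotted on x
is a display choice.

## The synthetic generator and what it shows

`generate_pair()` builds two inventories with known truth. Defaults are
the study conditions of the packaged pair: 9 and 13 clusters, 5 truly
shared, a type mix proportional to the observed one (t1pks 0.27, t2pks
0.18, t3pks 0.09, nrps 0.28, pks_nrps 0.18), module counts from a shifted
Poisson with mean 3 (matching the 1–10 modules-per-gene range seen in real
tables), and a 0.3 probability that an A domain lacks a substrate call.
Shared clusters are copied between strains under the same id and the
second copy is mutated per module at the divergence rate (substrate swap,
accessory-domain gain/loss, module insertion/deletion — all
type-preserving, since conservation is a within-type notion). Specific
clusters are drawn independently and rejection-sampled until they score
below 0.5 against everything in the other strain: without this the truth
would be ill-defined, because stereotyped architectures (type II, type
III) collide by construction. A consequence worth knowing: at most one
strain can hold a *specific* type III cluster, which is also how real
strain pairs look.

What passing tests on generated data do show: the inference machinery
recovers a known truth exactly at zero divergence (100/100 random
configurations), degrades monotonically with divergence, and the RC-vs-dDDH
concordance behaves as hypothesized when the ground truth couples them.
What they do not show: performance on real homology, where conservation is
a sequence-identity judgement and architecture is only its shadow — real
conserved clusters can differ more than the 0.7 threshold tolerates (the
recovery simulation quantifies exactly this failure mode), and real expert
maps should override inference.

## Numerical and degenerate-input choices

- Rounding is half-up (`round_half_up()`), not banker's, to match printed
  percentages.
- The alignment and assignment are deterministic; identical inputs give
  byte-identical outputs, and generator output is a pure function of its
  seed.
- Degenerate inputs are typed errors, not silent results: unknown domain
  tokens name the offending token, empty modules (consecutive hyphens),
  duplicate cluster ids, non-one-to-one conservation maps, maps citing
  unknown ids, prealigned sequences of unequal length, regression with
  fewer than three complete cases.
- An empty inventory is valid (zero clusters) and round-trips through the
  file format.
- ORF sizes (`>375` lower bounds, `1,446` thousands separators) are parsed
  and preserved but never compared: they are descriptive metadata.

## Problem sizes

The shipped analyses and tests run on the two packaged inventories (22
clusters, ≤ 18 modules per cluster), 1000-string grammar samples, 100
random generator configurations for the zero-divergence recovery check,
and 20 replicates per divergence level for the recovery curve — sizes
chosen to exercise every code path while keeping the whole suite
interactive on a laptop.

## Known limitations

- Architecture-based similarity cannot separate clusters whose biosynthetic
  difference lives in sequence, not architecture (the type II ambiguity
  above); expert maps exist for precisely this reason.
- Backbone prediction ignores tailoring, stereochemistry, macrocyclization
  and starter-unit chemistry, and does not predict A-domain specificity
  from sequence — substrate calls are input annotations.
- The assembly-line order of heavily fragmented clusters spread over many
  scaffold-terminal ORFs is not reconstructable from the inventory alone;
  such clusters (known-product in the packaged data) are not given
  predictions.
- dDDH/ANI are never computed from genomes here; the concordance module
  analyses supplied values only.
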