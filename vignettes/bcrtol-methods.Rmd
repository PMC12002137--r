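---
title: "Models and methods behind bcrtol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bcrtol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what each stage
assumes, which parameters matter and why their defaults are what they are,
what the synthetic-data generator does and does not emulate, and where the
methods are known to be approximate. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The scientific setting

In autoantibody-mediated disease, the receptors of antigen-reactive B cells
carry the history of the tolerance checkpoints they crossed: a naive
compartment seeded by central tolerance, and a memory compartment gated by
peripheral tolerance and germinal-center selection. The quantities this
package computes — reactive-well frequencies per compartment, the unmutated
ancestors of memory receptors, clonal structure, binding kinetics of mutated
versus ancestral antibodies, and epitope bins — are the standard readouts
used to locate where tolerance failed and what somatic hypermutation (SHM)
contributed.

## Coordinates and conventions

All coordinates are 0-based, half-open; anchors are 0-based codon start
positions. The *junction* runs from the first base of the V segment's
conserved 2nd-CYS codon through the last base of the J segment's Trp/Phe
codon, inclusive; the *CDR3* is the junction translation minus those two
anchor residues. A single convention everywhere is the cheapest defense
against junction off-by-one errors.

## Germline reference

The annotator and simulator are reference-agnostic: any V/D/J segment set
can be supplied as FASTA plus a metadata sidecar (name, locus, segment
type, anchor, reading frame), and `validate_germline_db()` enforces the
structural invariants (ACGT alphabet, anchor codons translating to
Cys / Trp / Phe, frame congruence, no D segments on light-chain loci,
unique names). The shipped reference is **synthetic** — deterministically
generated sequences with realistic lengths (V ≈ 290–300 nt, D 14–30 nt, J
48–57 nt) and valid anchors — so the package carries no licensed reference
data; curated alleles drop in through the same loader, and the reference's
version tag is echoed into every AIRR output.

## The repertoire simulator

`simulate_repertoire()` is a first-class, tested module: every downstream
stage is benchmarked against its ground truth.

* **Recombination.** V, (D,) J drawn uniformly per locus; geometric
  exonuclease trimming per segment end (`trim_mean`, default 2 nt);
  Poisson-length N inserts of uniform bases (`n_insert_mean`, default 4 nt)
  at the V–D and D–J (heavy) or V–J (light) joins. Draws are rejected until
  productive: both anchor codons survive trimming, sit in a common reading
  frame, and the in-frame translation carries no stop codon. More than
  1000 consecutive rejections aborts with an error (degenerate
  configuration).
* **SHM.** Uniform per-site substitution at the configured rate, each hit
  replaced by a uniformly chosen different base. Naive cells default to
  rate 0; memory clones draw a per-clone rate uniformly from 0.02–0.06 per
  nucleotide (≈ 8–25 substitutions on a ~400 nt variable region). No
  hotspot model: the analyses consume mutation *counts*, not spectra, so
  hotspot weighting is left as an extension point.
* **Clonal structure.** Clone sizes are geometric (`clone_size_p`, default
  0.5); a clone shares one rearrangement and one clone-level SHM pass, and
  each member then accumulates independent extra SHM at a quarter of the
  clone rate — similar but non-identical members, so clonal partitioning is
  testable on non-trivial clones.
* **Labels.** Reactivity is an independent per-cell Bernoulli draw
  (default 0.5%, the order observed for autoantigen-reactive naive B
  cells); group and compartment are factor labels.

What the generator does *not* emulate: selection during affinity
maturation (memory receptors are not re-checked for productivity after
SHM, so a realistic fraction acquires stop codons), physical heavy/light
pairing beyond a shared cell ID, isotype switching, and allele-level
polymorphism. Passing benchmarks on these simulations therefore
demonstrates algorithmic correctness against known truth — not performance
on the full complexity of real repertoires.

## Annotation

V genes are assigned by local alignment (match +1, mismatch −1, gap open
−4, gap extend −1 — exposed in `annot_config()`), ranked by score with ties
broken by identity then name. Floors: V identity 0.60 over at least 100
aligned nt (a local alignment of unrelated sequence keeps only a short
high-identity island, so the length floor does the real rejection work); J
identity 0.70 over at least 15 nt, searched 3′ of the V block on the V's
locus. Because a local aligner clips terminal mismatch runs, the winning
block's column map is extended ungapped to the segment ends (rightward only
through the V anchor codon); without this, substitutions at clipped segment
ends would silently vanish from mutation calling and reversion.

D genes are sought only inside the junction interior (junction minus the
two anchor codons), as the best ungapped ±1 run on the given strand,
reported at ≥ 9 nt and ≥ 0.75 identity; inverted-D rearrangements are out
of scope. Mutations are every mismatched aligned column in the V block up
to the end of the V anchor codon and in the J block from the J anchor
codon, classified replacement/silent by codon translation in the germline
frame; the junction interior is excluded, and gapped columns are tallied as
indels, not mutations, and never reverted. Every mismatch against the
supplied reference counts as a mutation — established polymorphisms are not
distinguished from SHM, which is a documented difference from annotation
services that fold in allele databases.

## UCA reversion

The unmutated common ancestor is reconstructed per receptor
(substitution-only, length-preserving): templated V/J mismatches revert to
germline; the heavy-chain junction is re-searched with the D assigner and
mismatches within the best-aligned D match revert to the D germline base;
all other junction-interior nucleotides are non-templated and left
unmodified. Two modes exist because the procedure's natural-language
description is ambiguous about silent mutations: the default
`all_substitutions` leaves no silent mutations in a putative germline
ancestor; `replacement_only` takes the literal reading. The per-sequence
count of untouched junction nucleotides quantifies the intrinsic limit:
junctional diversity cannot be recovered by reversion.

Two boundary effects are worth naming. First, V-template nucleotides 3′ of
the V anchor codon and J-template nucleotides 5′ of the J anchor lie inside
the junction interior, where only the D search operates; mutations there
are irrecoverable by construction. Second, under junction SHM the D match
can re-align at a slightly shifted offset, so D-guided reversion
occasionally writes a D-germline base at a position that was not mutated
(and, more rarely, coincidentally restores an N-region hit it overlaps).
Measured on seeded simulations, recovery of templated positions outside the
junction interior is exactly 100%, every discrepancy is confined to the
junction interior, and the non-SHM discrepancies are confined to the
D-reverted interval — the precise form of the "best aligned D gene" rule's
ambiguity.

## Clonal partitioning

Sequences group when they share V gene and J gene (alleles ignored — robust
to allele miscalls), junction length, and junction identity at or above the
threshold (default 0.85), closed under single linkage (connected
components). This replaces an unspecified spectral-clustering step with the
deterministic, standard approach to BCR clonotyping; the threshold is
exposed. Raising the threshold can only refine the partition. Clone
*recovery* is benchmarked on heavy chains: light-chain junctions carry a
single short N insert over a handful of germline genes, so junction
identity cannot separate light-chain clones (measured per locus, lambda
recovery collapses while heavy-chain recovery is exact) — the same reason
repertoire practice defines clones on heavy chains.

## Checkpoint statistics

The Fisher exact test uses the minimum-likelihood two-sided convention —
the sum of hypergeometric point probabilities not exceeding the observed
table's, with a 1e-12 relative tolerance in the comparison so exact ties
survive floating point — because that convention reproduces the published
p-values on the published tables and is the widespread default. A zero
outcome margin returns p = 1 by convention. The implementation is checked
in the tests against exhaustive enumeration over all tables with N ≤ 30
and against `stats::fisher.test`.

Frequencies carry exact Clopper–Pearson intervals (via
`stats::binom.test`). CDR3 net charge uses the integer rule at neutral pH
(R, K = +1; D, E = −1; H = 0), configurable since no single convention is
universal. V-family goodness of fit takes its reference proportions as an
input table — they come from external repertoire surveys, not from this
package. KD fold changes are summarised by the geometric mean (folds are
ratios); an arithmetic option exists because published "mean fold" figures
rarely state their averaging.

## SPR kinetics

Single-cycle traces follow the piecewise closed-form 1:1 Langmuir solution:
during an injection at concentration C the response relaxes toward
`Req = kon·C·Rmax / (kon·C + koff)` at rate `kon·C + koff`; between and
after injections it decays at `koff`; the response is continuous across
boundaries. Mass-transport limitation is deliberately not modeled — the
target analysis fits a plain 1:1 model, and the instrument's transport
constant setting is not reproducible from its description. Baseline
subtraction is assumed done; a linear-drift nuisance term is available as a
flag.

Fitting runs Levenberg–Marquardt on (log10 kon, log10 koff, log10 Rmax)
from a log-spaced multi-start grid (kon 1e3–1e7, koff 1e-5–1e-1): affinities
span six orders of magnitude, and single-start fits in natural parameters
are initialisation-sensitive. `kd = koff/kon` holds exactly in every
returned fit, and `converged` is false when the residual RMS exceeds five
times the noise floor (known simulation noise, or a difference-based robust
estimate). The recovery benchmark draws KD log-uniformly over
1.5e-10–1.7e-4 M with per-trace koff log-uniform on 3e-4–3e-2 s⁻¹ (the
window the 120 s injection / 600 s dissociation schedule can actually
resolve), kon = koff/KD, six twofold dilutions topping at 10·KD, and 2%
Gaussian noise — the package's emulation of how an experimentalist brackets
an expected affinity; with fixed concentrations far from KD the problem
becomes unidentifiable regardless of fitter quality. Endpoint dilutions use
the first-crossing rule, with a flag when a series re-crosses the
threshold.

## Epitope binning

Percentage inhibition is the percentage reduction from maximal binding,
`PI[i,j] = 100 (1 − F[i,j]/F_iso[j])`; negative values (enhancement) are
reported raw but floored at zero for binning. Antibodies join one bin when
the larger of their two directed PI values reaches the threshold (default
50%, exposed — no published cutoff exists), and bins are connected
components; `min` symmetrisation is available for a stricter mutual-
competition rule. The directed edge list is kept so asymmetric competition
stays visible; force-directed layouts are presentation, not inference.

## Problem sizes and numerical choices

The test suite and acceptance script use: 500 simulated memory-load
sequences for UCA recovery (per-clone SHM rates uniform on 0.012–0.095 per
nucleotide so per-record templated loads span ~5–38, matching published
heavy-chain mutation counts); 200–250 sequences for annotation accuracy at
rates 0 and 0.02; 160 heavy-chain sequences for clone recovery; 100 noisy
traces for KD recovery; exhaustive enumeration to N = 30 for the Fisher
oracle. These sizes give stable benchmark estimates while keeping the whole
suite interactive. All simulations are seeded; identical configurations
produce byte-identical outputs.

## Known limitations

* No indel handling beyond flagging: gapped columns are counted but never
  reverted, and alignments with indels take a slower mapping path.
* Polymorphism vs SHM is not distinguished; counts are relative to the
  supplied reference.
* The simulator's SHM is hotspot-free and selection-free; mutation spectra
  and post-SHM productivity rates are not realistic.
* Light-chain clonotyping is structurally weak (see above); the package
  computes it but benchmarks clones on heavy chains.
* The 1:1 kinetic model ignores mass transport, bivalent analytes and
  heterogeneous ligands; traces dominated by those effects will fit poorly
  and should be flagged by the convergence check.
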