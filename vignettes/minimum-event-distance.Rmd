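---
title: "Minimum-event distances and WGD-aware copy-number phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-event distances and WGD-aware copy-number phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmed)
```

## The problem

Somatic copy-number alterations (SCNAs) accumulate in tumor genomes as
gains and losses of chromosomal segments, whole-genome doublings (WGD),
and loss of heterozygosity (LOH).  Reconstructing a tumor's evolutionary
history from the copy-number profiles of its samples (or single cells)
requires an explicit model of these events, because SCNAs violate the
assumptions behind generic distances: neighboring segments are
correlated (one event spans many segments), events overlap and cancel
(back-mutation), and fully deleted material can never be regained.

`cnmed` infers phylogenies from segmented haplotype-specific integer
copy-number profiles using the *minimum-event distance* (MED): the
smallest number of segmental gains, segmental losses, LOH-phase losses
and (optionally) WGD events that transforms one profile into another.

## The event model

A profile assigns each genomic segment two integer copy numbers, one per
parental haplotype, between 0 and a cap (default 8).  For the distance
computation, both haplotypes are concatenated into one symbol string
over the alphabet `{0..cap, X}`, with the separator `X` marking
chromosome boundaries.

The elementary events are:

* **segmental gain** — `+1` on a contiguous run of segments within one
  chromosome of one haplotype; zero-copy segments inside the run are
  skipped (the physical DNA is absent), and values at the cap saturate
  (the cap is an observation ceiling, consistent with clipping of input
  values above the cap);
* **segmental loss** — `-1` on a contiguous run; results stay at or
  above 1, and a run cannot span a single-copy segment (deleting it
  would be LOH);
* **LOH-phase loss** — a `-1` run that may take segments to 0;
* **WGD** — `+1` on every non-zero segment of the whole genome, both
  haplotypes, ignoring chromosome boundaries, at cost 1.

Events apply in a fixed phase order: LOH-phase losses, then WGDs, then
segmental losses, then gains.  LOH must come first because later events
skip zero-copy segments; WGDs must precede segmental losses and gains so
that, for example, segments gained by the doubling can subsequently be
lost.  The distance is defined over histories in this canonical order;
the order of events within a phase does not affect the count.

Each event class is realized as a weighted finite-state transducer over
the tropical semiring (weights add along a path; alternative paths take
the minimum).  A one-step transducer applies at most one event per
position; composing it with itself n times spans events of any depth,
with n chosen from the alphabet size so that every copy-number change
within the cap is reachable.  The asymmetric MED between profiles x and
y is the shortest distance through

    x ∘ T_LOH ∘ T_WGD ∘ T_L ∘ T_G ∘ y

and is genuinely asymmetric: it is infinite when y has copy number where
x has none.  The symmetric distance used for tree building routes
through an unobserved common ancestor z,

    S[x, y] = min_z med(z, x) + med(z, y),

computed as the shortest distance through the kernel composition of the
chain with its inverse; the intermediate symbols of an optimal path
decode into a witnessing ancestor profile.

### Numerical realization

Materializing the composed transducer is infeasible, so shortest paths
are computed lazily.  Two exact devices make this fast:

1. **Closed-form n-step machines.**  The n-fold self-composition of a
   one-step event machine is weight-equivalent to a small "run-counting"
   automaton whose state is the number of currently open event layers
   (opening a layer costs 1; continuing, closing, and skipping zeros are
   free).  This replaces `2^n` states by `n + 1`.  The equivalence is
   asserted against literal self-composition in the test suite.  One
   subtlety is inherited from the layered semantics: when earlier LOH
   layers drive a value to 0, the remaining open layers skip that
   position, so a stack of LOH runs can zero a multi-copy segment while
   continuing across it.
2. **Separator factorization.**  Segmental machines are forced back to
   their idle state at every `X`, and only the WGD count spans the
   genome.  Conditional on the WGD counts, the distance therefore
   factorizes exactly into independent per-chromosome-per-haplotype
   pieces, each solved by a tiny dynamic program over open-layer counts
   with monotone dominance pruning (more open layers at no greater cost
   can always mimic fewer), iterative deepening on the cost budget,
   per-position lower bounds, and memoization of piece solutions across
   all pairs of a cohort.  The conditioned sums are then minimized over
   the WGD grid.

Both devices are exact reformulations, not approximations; the test
suite checks them against the generic transducer engine
(`chain_shortest_path()`) and against a breadth-first-search oracle that
enumerates explicit phase-ordered event sequences on tiny genomes.
Distances are exact integers throughout (stored in doubles, with `Inf`
as the unreachable sentinel).

## Evolutionary phasing

Allele-specific copy-number callers report unordered major/minor values.
When multi-sample phasing is unavailable, `evolutionary_phase()` assigns
major/minor to haplotypes A/B at every segment so that
`med(diploid, hapA) + med(diploid, hapB)` is minimal, each haplotype
scored as its own genome.  The `2^n` assignments form an unweighted
phasing transducer (two transitions per segment), and the optimum is a
shortest path through the diploid-rooted event chains on both sides;
the implementation solves the same problem per chromosome conditional
on the two per-haplotype WGD counts, which is an exact factorization.
The optimum is exact (verified against exhaustive search up to n = 12);
among ties, assignments keeping the major allele on haplotype A are
preferred, with remaining ties broken deterministically by the engine.
Swaps are allowed at every segment boundary; since no event crosses a
chromosome boundary, one genome-wide pass equals per-chromosome passes.

## Trees, ancestors, events

* **Topology** comes from neighbor joining (via `ape::nj`) on the matrix
  of pairwise symmetric MEDs, including the diploid; negative NJ branch
  lengths are clamped to zero with a warning.
* **Rooting** places the root on the diploid's pendant branch.
* **Ancestral genomes**: internal nodes are initialized bottom-up with
  symmetric-MED pair ancestors, then refined by a monotone local search
  (candidates: current profile, pair ancestors with parent and children,
  and the neighbor profiles; strict improvements only), so the total
  number of events along the tree never increases and the search stops
  at a local minimum.  A coordinate-wise refinement over disagreeing
  segments is available (`coordinate_refine = TRUE`) and used in tests
  on small inputs, where the local search provably attains the
  exhaustive Steiner optimum; it is off by default because its cost
  grows with genome length while the candidate search already attains
  the optimum in the cases we can verify exhaustively.  Exact global
  Steiner optimization is NP-complete and out of scope.
* **Branch lengths** are the asymmetric MEDs from parent to child after
  reconstruction, so the tree length equals the total number of inferred
  events; `extract_events()` decodes one optimal path per branch into an
  event table whose replay reproduces the child exactly.  The reported
  decomposition is one deterministic optimum among possibly many.
* **WGD detection** uses the evidence score
  `s = MED_noWGD(diploid, t) - MED_WGD(diploid, t)` (non-negative by
  construction; `s >= 1` prefers a doubling), and the WGD count is the
  smallest n at which the n-WGD-bounded distance matches the unbounded
  one.  Chromosome-bootstrap replicates (whole chromosomes drawn with
  replacement; valid because events end at chromosome boundaries and
  WGD ignores chromosome identity) give a replicate fraction; a sample
  is called WGD-positive when at least 5% of replicates (configurable)
  show at least one WGD.
* **Branch support** is the percentage of replicate trees containing
  each bipartition; the segment jackknife (N draws with replacement,
  duplicates discarded, order preserved — on average discarding a 1/e
  fraction) is the faster alternative to the chromosome bootstrap.
* **Region scores** count, per region of interest, the tree events whose
  genomic span covers at least 90% of the region (gains minus losses;
  genome-wide WGD events count as a gain for every region).  The
  overlap is measured as the covered fraction *of the region*: regions
  of interest (genes, arms) are typically small relative to events, so
  the opposite reading would almost never trigger for gene-sized
  regions.

## The simulators

Two generators produce all validation data; no external dataset is
required.

**MED-model simulator** (`simulate_profile_with_known_count()`): applies
`k ~ Poisson(mu = 10)` model events to the diploid on a genome of 5
chromosomes with 10 segments each; each event is a WGD with probability
5% and otherwise a gain or loss (47.5% each); starts are uniform over
non-zero positions, lengths geometric with p = 0.2, and events respect
the model's constraints (no gains of zero-copy segments, termination at
chromosome boundaries except for WGD).  Because every simulated event is
a model event and +1-per-segment WGDs commute with segmental events,
the inferred MED is a true lower bound on `k`.

**Genome-level simulator** (`evolve_genomes()`): to avoid biasing
benchmarks toward the distance model, evolution is simulated on an
explicit token representation of the genome (each physical segment
remembers which reference segment it descends from), along a random
topology built by uniform sequential joining and rooted at the diploid.
Per branch, the event count is `Poisson(lambda)` with
`lambda = delta_t * S * mu` (`delta_t = 1`, `S = 440` segments over both
haplotypes by default).  Events include whole-chromosome gains and
losses, focal losses, insertions (a duplicated contiguous run inserted
at a random position — the literature leaves the mechanism open, and a
tandem-like duplication is the simplest copy-gaining insertion),
breakage-fusion-bridge cycles (terminal loss plus inverted duplication
of the new terminus — the canonical BFB outcome), WGD, and copy-neutral
inversions and balanced/unbalanced translocations.  All types are
equally likely except BFB at a relative weight of 0.1 and WGD at its own
probability (0 / 0.0125 / 0.065 for the no/low/high settings, 0.000125
for large trees).  Deletion-type events never target chromosome units
founded from haplotype 2, which prevents homozygous deletions (we read
the constraint as banning all deletion classes on that haplotype, since
any of them could produce a homozygous loss).  Relocated segments are
subsequently gained and lost with their host chromosome, so profiles
derived by counting segment copies reflect positional coupling.
Copy-neutral events change segment order but not the derived profiles,
which deliberately violates the model's contiguity assumption.  Each
branch consumes a deterministic substream of the seed, so a topology
change does not scramble unrelated branches.

What these simulations do *not* emulate: measurement noise in copy
number calls (logR/BAF noise, segmentation error), subclonal mixtures
within a sample, and chromothripsis-like single catastrophes beyond
BFB.  Passing the simulation-based tests therefore certifies the
method's behaviour under clean, correctly segmented input, not
robustness to caller noise.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cap` | 8 | largest representable copy number; inputs above it are clipped with a warning, and the alphabet, composition depths and saturation derive from it |
| `wgd_enabled` | `TRUE` | include the WGD event class |
| `max_wgd` | `cap` | bound on the number of WGDs the model may invoke |
| `loh_steps`, `seg_steps` | `cap + 1`, `cap` | self-composition depths of the event machines (alphabet size minus 1 and minus 2); the defaults span every reachable change within the cap |
| `B`, `threshold` | 100, 0.05 | bootstrap replicates and WGD calling threshold |
| `mu`, `p_wgd`, `p_geom` | 10, 0.05, 0.2 | MED-simulator event rate, WGD share, run-length parameter |
| genome simulator `mu`, `wgd_prob` | 0.025, 0.0125 | per-segment per-branch rate and WGD probability |

Problem sizes used by the validation suite are chosen to run on a single
CPU in minutes: oracle comparisons use genomes of up to 8 segments at
cap 3 (where exhaustive search is feasible), phasing optimality is
verified to n = 12 (4096 assignments), and the tree-recovery benchmark
simulates 25 trees per leaf count in {5, 10, 15, 20} at mu = 0.025.

## Degenerate inputs and edge cases

* Profiles that disagree on segmentation are rejected with a pointer to
  `harmonize_segmentation()`, which intersects all breakpoints.
* Sex chromosomes are dropped on input by default (`include_sex` keeps
  them).
* A profile with copy number where another has zero has infinite
  asymmetric distance; the symmetric distance is always finite (the
  ancestor can carry the material), and the pipeline reports, rather
  than silently drops, any infinite pair.
* The jackknife on a single-segment genome degenerates and warns; the
  chromosome bootstrap on a single-chromosome genome returns the
  original cohort in every replicate.
* Ties between equally parsimonious paths, ancestors and phasings are
  broken deterministically, so identical runs produce identical
  outputs; the specific optimum reported is otherwise arbitrary.

## Known limitations

* The MED treats every elementary event as equally costly; complex
  rearrangements are represented by their elementary footprint.
* Ancestral reconstruction is a local search with a monotonicity
  guarantee, not a global Steiner optimum.
* Counting each post-WGD chromosome loss separately can overestimate
  the true number of biological events in heavily rearranged
  tetraploid-descended genomes.
* The contiguity assumption (segments keep their reference order) is
  violated by translocations and inversions; simulations show the
  distance degrades only mildly, but heavily rearranged genomes blur
  event boundaries.

## A worked miniature

```{r example}
lay <- uniform_layout(2, 4)          # two chromosomes, four segments each
dip <- diploid_profile(lay)
tumor <- cn_profile("t", hapA = c(2, 2, 2, 2, 2, 2, 2, 2),
                         hapB = c(2, 2, 0, 0, 2, 2, 2, 2))
model <- build_event_model()
med_asymmetric(dip, tumor, model, lay)
extract_events(dip, tumor, model, lay)
wgd_evidence(tumor, lay)[c("s", "wgd_count")]
```

One WGD plus one LOH-phase loss explain the doubled, partially LOH
genome; without the WGD event class the same profile would require one
gain run per chromosome copy.
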