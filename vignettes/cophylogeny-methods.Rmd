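---
title: "Testing host-parasite co-diversification from partial marker sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing host-parasite co-diversification from partial marker sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procophy)
```

## The problem

Microsporidian parasites such as *Dictyocoela* infect amphipod crustaceans
across wide geographic ranges, and a recurring question is whether the
parasites diversified *with* their hosts (co-diversification) or jumped
between host lineages (host shifts). The molecular evidence is usually a set
of parasite SSU rDNA sequences and host barcode (COI) haplotypes, with one
complication that shapes everything downstream: the parasite sequences come
in nested fragments of heterogeneous length (roughly 350, 530 and 800 bp,
sharing a 5' primer), so the data are partial sequences on a common
alignment, not a tidy rectangular matrix.

`procophy` implements the full chain from such data to a co-diversification
verdict:

1. **Haplogrouping** of variable-length sequences by diagnostic sites, with
   explicit multi-candidate assignments for fragments too short to be placed
   in a single group.
2. **TN93 genetic distances** under pairwise deletion, for both parasite and
   host matrices.
3. A **Procrustean co-phylogeny test**: principal coordinates of both
   distance matrices, Procrustes superimposition of the parasite
   configuration onto the host configuration across the association links, a
   global goodness-of-fit statistic $m^2_{XY}$, permutation significance, and
   jackknife per-link residuals.
4. **Conservative handling of ambiguity**: one association matrix per
   combination of candidate haplogroups, reporting the alternative with the
   largest P value.
5. A **synthetic co-diversification simulator** providing ground truth for
   every stage.

## Haplogroups from partial sequences

Reducing mixed-length sequences to a common length either discards the long
fragments' signal or the short fragments themselves. The haplogroup approach
keeps both: sequences belong to distinct haplogroups when they differ at one
or more *diagnostic sites* within shared coverage, and sequences identical
over their entire (possibly short) coverage fall in the same group.

`build_haplogroups()` makes this operational with a greedy, deterministic
rule: sequences are processed longest-first (ties by label) and compared to
existing group representatives over comparable sites only (both sequences
carrying `A`, `C`, `G` or `T`; gaps, `N` and padding are excluded pairwise).
A sequence that mismatches every representative founds a new group; one that
matches exactly one joins it; one that matches several is recorded as
*ambiguous* — a candidate of all matching groups and a member of none.
Longest-first processing guarantees that representatives are the
maximal-information (longest) members and never change afterwards, which
makes the procedure order-independent given the rule, and re-runs
bit-identical.

Two consequences worth noting. First, ambiguity is monotone under
truncation: shortening a sequence can only grow its candidate set (it can
never create a mismatch). Second, the inventory of groups can in principle
depend on the processing order of equally long sequences; the lexicographic
tie-break fixes one canonical order, and inventories from other defensible
orders may differ by one group in edge cases. This is inherent to any greedy
reading of the haplogroup definition.

Species labels are attached by `assign_species()` via the nearest labeled
reference under TN93 distance — a distance-based surrogate for
phylogenetic placement that is fast and directly testable. Assignments
beyond a configurable distance threshold (default 0.10 substitutions/site,
comfortably above within-species and below between-species divergence for
these markers) are reported `unassigned`; exact ties between species are
broken by the smaller mean distance to all of each species' references.

## TN93 distances under pairwise deletion

The Tamura-Nei (1993) model distinguishes the two transition types (A/G,
C/T) and transversions under unequal base frequencies — the substitution
model these ribosomal and mitochondrial markers typically select. For each
pair, `tn93_pair_stats()` tallies the proportions $P_1$ (A/G differences),
$P_2$ (C/T differences) and $Q$ (transversions) over comparable sites, and
the distance is the closed form

$$d = -\frac{2 g_A g_G}{g_R}\ln w_1 - \frac{2 g_T g_C}{g_Y}\ln w_2
      - 2\Big(g_R g_Y - \frac{g_A g_G g_Y}{g_R} - \frac{g_T g_C g_R}{g_Y}\Big)\ln w_3$$

with $g_R = g_A + g_G$, $g_Y = g_C + g_T$, $w_1 = 1 - g_R P_1/(2 g_A g_G) -
Q/(2 g_R)$, $w_2 = 1 - g_Y P_2/(2 g_T g_C) - Q/(2 g_Y)$, $w_3 = 1 - Q/(2 g_R
g_Y)$.

Two conventions are deliberate and documented because other software differs:

* **Base frequencies are pooled per pair** over the comparable sites of the
  two sequences, not taken from the whole alignment. When fragments cover
  different regions, global frequencies would mix information from columns a
  pair never shares. (With exactly two sequences the conventions coincide,
  which is how the implementation is cross-checked against `ape::dist.dna`.)
* **Pairwise deletion, not complete deletion.** The entire point of the
  haplogroup strategy is to retain short fragments; complete deletion would
  discard most columns of the alignment.

Saturated pairs (any logarithm argument non-positive) yield `NA` with a
warning rather than an error, keeping the distance step total; the
ordination step refuses incomplete matrices loudly, so missingness cannot
propagate silently.

## The Procrustean co-phylogeny test

The test asks whether the parasite distance structure, read through the
host-parasite association links, is a better fit to the host distance
structure than random association would produce. It needs no resolved trees
— only distance matrices — which suits datasets whose parasite phylogeny is
partly unresolved.

**Ordination.** Each distance matrix is embedded by classical principal
coordinates (`pcoa()`): Gower double-centering of $-\tfrac12 D^{(2)}$,
eigendecomposition, and retention of axes with eigenvalue
$> 10^{-8} \times$ the largest. Negative eigenvalues (non-Euclidean input)
are dropped by default, the common practice for this test; a Cailliez
correction is available (`correction = "cailliez"`) for users who prefer
exact embeddability. The ordination is computed once per matrix —
permutations and jackknife deletions act on links, never on distances.

**Link expansion and superimposition.** For $L$ links, row $\ell$ of $X$
holds the host coordinates of link $\ell$ and row $\ell$ of $Y$ its parasite
coordinates (a host in several links contributes duplicated rows); the
narrower matrix is zero-padded to the common width and both are
column-centered. Procrustes superimposition fits $Y$ onto $X$ with rotation
and uniform scaling: with $Y^\top X = U \Sigma V^\top$, $R = U V^\top$ and
$c = \mathrm{tr}\,\Sigma / \mathrm{tr}(Y^\top Y)$, giving

$$m^2_{XY} = \mathrm{tr}(X^\top X) - \frac{(\mathrm{tr}\,\Sigma)^2}{\mathrm{tr}(Y^\top Y)}
           = \sum_\ell \lVert X_\ell - c\,Y_\ell R \rVert^2 .$$

The implementation computes both sides and asserts their agreement at
$10^{-9}$; the per-link decomposition is exact by construction.

**Permutation null.** "Random association" is operationalised by applying a
uniform random permutation to the host components of the link list, keeping
the parasite components fixed — this preserves $L$ and the per-parasite link
multiset, and is the simplest faithful reading of assigning hosts randomly
to parasites. The P value uses the add-one convention
$p = (1 + \#\{m^2_{perm} \le m^2_{obs}\})/(n_{perm} + 1)$, ties counting
toward the numerator, so $p \ge 1/(n_{perm}+1)$ and exact ties (e.g. the
identity permutation) cannot produce $p = 0$. One user-visible seed controls
the stream; `conservative_paco()` offsets it deterministically per
alternative so a whole multi-hypothesis analysis reproduces from a single
integer.

**Jackknife link residuals.** The contribution of each link is assessed by
leave-one-link-out: deleting link $j$, re-centering, refitting, and forming
pseudovalues $\nu_{ij} = L r^2_i - (L-1) r^2_{i(-j)}$ for each remaining
link $i$. A link's estimate is the mean of its pseudovalues, truncated below
at zero (a squared residual cannot be negative), and its one-sided upper 95%
bound is $\text{estimate} + t_{0.95,\,L-2}\,\mathrm{SE}(\nu_{i\cdot})$.
Links with small estimates carry the co-phylogenetic signal; links created
by host shifts stand out with large ones.

**Ambiguity enumeration.** Every ambiguous observation (candidate set of
size $> 1$) multiplies the set of admissible association matrices;
`association_data()` enumerates the product (capped at 64 by default — the
cap exists because the enumeration is exponential and a dataset needing more
deserves manual curation) and `conservative_paco()` reports the alternative
with the **largest** P value, so the published claim is the one every
reading of the data supports.

## The synthetic simulator

`simulate_scenario()` generates the study conditions with known ground
truth:

* **Host tree**: Yule (pure birth), rescaled to a root-to-tip depth of 0.15
  substitutions/site by default — deep enough that 16 host lineages are
  clearly differentiated at a 650-bp barcode, matching strongly structured
  host clades.
* **Parasite tree**: a copy of the host tree (perfect co-divergence)
  followed by a chosen number of tip prune-and-regraft moves, each moving
  one distinct parasite tip to a uniformly chosen position while keeping the
  tree ultrametric. A moved tip keeps its host link — precisely the
  incongruence signature of a host shift followed by specialisation. The
  parasite/host rate ratio is a parameter (default 1, there being no strong
  prior for these markers).
* **Sequences**: evolved site-independently under TN93 with the rate matrix
  normalised so branch lengths are expected substitutions/site (verified by
  an estimator-consistency test). Defaults: transition/transversion
  multipliers of 4 and mildly AT-rich frequencies (0.26/0.22/0.24/0.28),
  typical of these markers; host 650 bp (COI barcode), parasite 800 bp
  (longest SSU fragment).
* **Fragments**: parasite sequences optionally truncated to 5'-anchored
  fragments (all real fragments share the forward primer, so truncation is
  one-sided); the default mix of 1/6 at 350 bp, 1/6 at 530 bp and 2/3
  full-length makes haplogroup ambiguity occur without dominating.

What the simulator does *not* emulate: rate heterogeneity across sites,
indels and alignment error, within-host parasite diversity, multiple
parasites per host lineage, and sampling noise in which hosts get screened.
Tests passing on simulated data therefore validate the statistical machinery
and its operating characteristics under the model, not robustness to
real-data artefacts such as misalignment.

## Numerical and design choices

* 0-based, half-open coverage coordinates throughout; padding `?` is
  distinct from the alignment gap `-` (missing data vs indel).
* PCoA axis retention at relative tolerance $10^{-8}$; degenerate (all-zero)
  matrices are an error, not a silent empty ordination.
* Permutation counts below 99 are refused unless forced — with fewer the
  attainable P values are too coarse to be useful.
* The permutation loop recomputes only what the permutation changes (the
  host configuration and the cross-product SVD), so $10^5$–$10^6$
  permutations are practical.
* Problem sizes used by the shipped checks — 16-tip scenarios, 500
  calibration replicates at 199 permutations, 100 power/diagnosis replicates
  at 999 permutations — were chosen as the smallest sizes at which the
  operating characteristics (type-I error $0.05 \pm 0.02$, power $\ge$ 0.95
  under full congruence, shift diagnosis $\ge$ 0.90) are stable.

## Limitations

* Nearest-reference species assignment is a surrogate for phylogenetic
  placement; it inherits the reference set's coverage and will misassign
  queries from unsampled sister taxa.
* The greedy haplogroup rule is one defensible reading of the
  diagnostic-site definition; inventories can differ by ±1 group from other
  orderings when fragment chains are involved.
* The permutation scheme fixes the parasite side of the links; other null
  models (permuting parasites, or both) are not implemented.
* Jackknife confidence bounds use the classical pseudovalue normal
  approximation with $t_{0.95, L-2}$; for very small $L$ they are rough.
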