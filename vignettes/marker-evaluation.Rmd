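---
title: "Evaluating a protein-coding marker gene: methods and design notes"
author: "markerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a protein-coding marker gene: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerscan)
```

# The problem

16S rRNA amplicon surveys resolve bacterial communities to roughly the
species level at best; within a genus like *Bacillus*, many species share
near-identical hypervariable regions and strains are indistinguishable.
A single-copy protein-coding housekeeping gene such as *gyrA* evolves
faster and can, in principle, separate species and even strains — if a
degenerate primer pair can amplify it across the group of interest.
`markerscan` packages the four computations this evaluation needs:
in-silico PCR under a degenerate-primer amplifiability rule, nucleotide
diversity profiles, reference-anchored variable-site profiling, and
mock-community resolution counting. All four run on synthetic data with
known truth, generated inside the package.

# In-silico PCR

## The amplifiability rule

A degenerate primer of length $k$ denotes the Cartesian product of its
per-position IUPAC sets; gyrA3-F (`GCDGCHGCNATGCGTTAYAC`) denotes
$3 \cdot 3 \cdot 4 \cdot 2 = 72$ exact 20-mers. A window $w$ of the
template binds the primer when

$$\max_{v \in \mathrm{expansions}} \; \#\{j : v_j = w_j,\; w_j \in \{A,C,G,T\}\} \;\ge\; \texttt{minMatch},$$

with `minMatch = 18` by default, no indels inside the site, and both
strands scanned. A template is amplifiable by a pair when a forward site
and a downstream reverse-complemented reverse site exist with product
length inside `[minAmpliconLen, maxAmpliconLen]`.

Because the expansions form a full product over positions, the maximum
over expansions equals the count of window positions whose unambiguous
base lies in the primer's per-position set. The scan is therefore
$O(k \cdot L)$ with no expansion loop, and provably identical to
maximising `matchCount()` over `expandDegenerate()` — the test suite
verifies this equivalence against a brute-force oracle.

Choices a user should know about:

* **Ambiguity in the target counts as a mismatch**, never as a wildcard.
  Targets are assemblies; an `N` there means uncertainty, and crediting it
  as a match would overstate amplifiability.
* **Matches need not be contiguous and need not touch the 3' end.** The
  count rule mirrors how a local-alignment screen scores a primer hit.
  Because a polymerase is in reality intolerant of 3'-terminal
  mismatches, `findBindingSites()` and `inSilicoPCR()` accept
  `contiguous = TRUE` and `anchor3 = N` for sensitivity analysis; both
  are strictly stricter filters, which the tests check.
* **Length bounds** default to 100–3000 bp. They are not part of the
  biological rule; they exclude pathological genome-spanning products and
  are configurable.
* When a template yields several products, all are reported; summaries
  call a sequence amplifiable when at least one product exists, and the
  resolution stage uses the leftmost product deterministically.

# Nucleotide diversity

`nucleotideDiversity()` computes
$$\pi = \frac{2}{n(n-1)} \sum_{i<j} \frac{d_{ij}}{L_{ij}},$$
the mean over unordered pairs of the per-pair proportion of differing
sites. A site enters $L_{ij}$ only if both sequences carry an unambiguous
base there (*pairwise deletion*); gaps and IUPAC ambiguity codes are
missing data. Pairs with $L_{ij} = 0$ drop out of the mean, and the
function returns `NaN` when every pair drops out. Popular desktop
implementations do not document their exact missing-data rule, so
`deletion = "complete"` (restrict all pairs to columns unambiguous in
every sequence) is available; the default is pairwise because it uses
strictly more of the data. On gap-free alignments the two agree.

`slidingWindowPi()` tiles the alignment with windows of 100 columns
stepped by 10 — the conventional profile parameters for marker-gene
comparisons — starting at column 1 while the window fits. Windows are
defined on alignment *columns*: gap columns lie inside the span but are
excluded per pair. The reported midpoint is
`start + windowSize/2 - 1`; published profiles sometimes plot at other
offsets (e.g. a first point at position 200 for a 100/10 window), which
cannot be reconstructed from window arithmetic alone, so the offset is a
parameter (`midpointOffset`) rather than a hard-coded convention.

The analytic anchor for testing: if each of $n$ sequences independently
mutates each site of one ancestor with probability $m$ (uniform over the
3 alternative bases), two sequences differ at a site with probability
$2m(1-m) + \tfrac{2}{3}m^2$. The suite simulates 200 replicates of 10
sequences × 500 nt at $m = 0.02$ and requires the mean estimate within 3
Monte-Carlo standard errors of the closed form. Since the generator holds
primer-site columns invariant by design, this comparison is made over the
mutable insert region, where the per-site expectation applies.

# Variable-site profiling

`variableSites()` anchors on one representative (reference) genome —
configurable, else the first record — and, over a fixed region of
alignment columns, records a mismatch wherever another genome's
unambiguous base differs from the reference's unambiguous base. Three
deliberate choices:

* **Fixed denominator.** Per-genome frequencies are
  $100 \cdot k / L_\mathrm{region}$ with $L_\mathrm{region}$ the fixed
  region length, *not* the per-genome count of comparable columns.
  Published polymorphism tables back-compute exactly this way (one
  mismatch in a 480-bp region = 0.21 %; 32 in 500 bp = 6.40 %), and a
  shrinking denominator would make frequencies incomparable across
  genomes.
* **Coordinates are 1-based inclusive** everywhere a user sees them, so a
  330–810 region spans 481 columns. Where a published region is
  described as "480 bp" the coordinate convention in the source is
  ambiguous (inclusive 481 vs half-open 480); `regionLength` is therefore
  an explicit parameter, and both readings are exercised in the tests.
* **Gap-vs-base columns are not variable sites.** Only base-vs-base
  differences count; indel handling is a different analysis. This is a
  comparability caveat when reproducing published counts whose convention
  is unstated.

Frequencies are computed in full precision and rendered at 2 decimals,
half-up (`0.2083… -> 0.21`); ranges print with an en-dash
(`summarizeSpecies()`).

# Mock-community resolution

`resolveCommunity()` runs in-silico PCR per member and partitions members
by exact amplicon identity. Identity is judged on the **insert** (primer
regions trimmed) by default: a degenerate primer writes its own sequence
variants into the product, so two strains differing only under a primer
would otherwise look distinguishable when their reads are not.
`keepPrimers = TRUE` restores full-amplicon comparison; a test
demonstrates the two can disagree by construction.

`annotateZotus()` assigns denoised amplicon variants to the reference of
highest ungapped identity over the end-trimmed common length. Ties —
which necessarily occur when two strains have identical marker regions —
yield `"unassigned"` rather than an arbitrary winner; pooling
(`poolAndCount()`) then conserves total reads while merging strains of
one unit, so unit-level read counts are well-defined even when
strain-level assignment is impossible. The default `minIdentity = 0.97`
is the customary OTU-level threshold; with denoised (zero-radius) inputs
it mainly guards against off-target reads.

# The synthetic-data generator

`generateCommunity()` emulates exactly the statistical structure the
analyses assume: a star phylogeny (one genus ancestor; species ancestors
are independent per-site mutants at `interDivergence`; strains at
`intraRate`; intra-genome 16S-like copies at `copySnpRate`), gap-free
equal-length sequences per marker, and one exact primer-pair expansion
embedded at known coordinates. Mutations never land inside primer sites,
so a species' compatibility flag alone decides amplifiability, and the
truth table (planted positions, labels, expected amplicon coordinates)
fully determines every downstream result — which is what the end-to-end
tests assert.

What it does **not** emulate, and hence what passing tests cannot show
about real data: recombination and non-star genealogies, indels and
alignment error, compositional bias, chimeras, PCR efficiency differences
between mismatched-but-amplifiable templates, and realistic read-quality
profiles (`generateReads()` applies iid substitution errors only). The
generator validates the *computations*; claims about real genera still
require real genome sets.

`syntheticMockCommunity()` is a labelled synthetic stand-in for a
defined eight-strain benchmark: eight 16S-like and gyrA-like genes built
so the V3-V4 amplicon collapses three strain pairs (five units) while the
gyrA3 amplicon resolves six units. It demonstrates and tests the
resolution machinery; the sequences are constructed, not the strains'
true genes.

# Problem sizes and determinism

The test suite and acceptance script run at desk scale by design:
oracle-equivalence on alignments up to 8 × 300, 200 star-topology
replicates of 10 × 500 nt, a 10-species × 3-strain genus for the
end-to-end truth check, 1,000 random templates for strand-symmetry, and
the 8-strain community — a few tens of seconds in total. Every stochastic
step is seeded; `communitySpec`, `generateReads` and the CLI take
explicit integer seeds, and identical seeds give byte-identical FASTA,
truth tables and reports.

# Known limitations

* The binding-site rule is a base-identity count; no melting temperature,
  ΔG or secondary-structure model is attempted, and indels inside a
  primer site are not considered.
* π carries no confidence interval; Watterson's θ, Tajima's D and
  haplotype statistics are out of scope.
* Multiple sequence alignment is consumed, never computed: gapped inputs
  must be pre-aligned, and the generator sidesteps alignment by producing
  gap-free equal-length loci.
* Genome downloading is out of scope; `readAccessionManifest()` defines
  the manifest format but fetches nothing.
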