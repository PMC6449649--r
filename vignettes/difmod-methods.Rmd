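---
title: "Detecting dif sites and dif modules in Acinetobacter replicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dif sites and dif modules in Acinetobacter replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difmod)
```

## The biological problem

The XerC/XerD tyrosine recombinases resolve chromosome dimers at a single
28-bp *dif* locus near the replication terminus of most bacterial
chromosomes. In *Acinetobacter*, plasmids frequently carry multiple
*dif*-like sites (p*dif* sites), and pairs of such sites can bound a cargo
gene, forming a "dif module" — a simple mobile genetic element whose
movement is thought to depend on Xer recombination. Chromosomes of the genus
additionally carry *dif* sites beyond the canonical *dif1*, and these
additional sites resemble the plasmid sites more than they resemble *dif1*.

`difmod` implements the computational side of this analysis as a reusable,
tested pipeline: site detection, module calling, mobility assessment, site
clustering, consensus/information-content profiling, and collection-level
summaries — together with a synthetic-replicon generator that supplies full
planted ground truth so every stage can be validated without any sequence
downloads.

## Site model and detection

A *dif* site is modelled as a fixed-length 28-bp element: an 11-bp
XerC-binding arm, a 6-bp central region, and an 11-bp XerD-binding arm. On
the forward strand of a replicon a site appears either in XerC/XerD arm
order ("CD") or in the reverse XerD/XerC order ("DC").

Detection is an exhaustive fixed-length scan. Every 28-bp forward-strand
window is scored by **ungapped Hamming identity** (matches / 28, `N` never
matching) against four sequences: the CD reference, the DC reference, and
their reverse complements. Because the reverse complement of one arm order
presents the other, the four comparisons make the scan exactly
strand-symmetric: scanning the reverse complement of a replicon yields the
same sites with orientations swapped and coordinates mirrored. Windows at or
above `min_identity` become hits; overlapping hits are resolved to the
single best call (highest identity, then leftmost, then CD before DC — one
physical site, one call), and circular replicons are scanned across the
origin by default.

We use ungapped identity rather than a local aligner deliberately: the
element has a fixed 28-bp architecture, so a gapless scan is deterministic,
exhaustively complete, and trivially reproducible, whereas local-alignment
scores depend on aligner parameters and may score partial windows. The
default threshold is **0.75**, the lower bound of the customary "75–80%"
screening range for these sites; at 28 bp this means at least 21 matching
positions. Raising the threshold can only remove hits (a property covered by
tests).

### Expected chance hits

With i.i.d. background at 40% GC, the probability that a random window
reaches 21/28 against one AT-rich 28-mer is about `3e-7`
(binomial tail at a per-position match probability of ~0.28); across four
reference variants this gives roughly one chance hit per megabase scanned.
These marginal hits sit at the 0.75 boundary and are an inherent property of
the published threshold, not a defect of the scanner; the synthetic-data
tests bound them with the same analytic tail computation.

### Reference sites

The packaged reference pair (`inst/extdata/pdif_reference_synthetic.fa`) is
a **synthetic consensus-style pair**: the CD record carries the widely
reported *Acinetobacter* p*dif* arm architecture
(`ATTTCGTATAA|GGTGTA|TTATGTTAATT`) and the DC record is its reverse
complement with two arm substitutions, so that — as with the natural
reference pair — the two references are distinct sequences presenting
opposite arm orders. Any user-supplied 28-bp pair can be passed instead
(`reference_sites(path)`); all pipeline behaviour is defined relative to
whichever pair is supplied. The chromosomal *dif1* reference used by
`classify_chromosomal_sites()` is likewise a Proteobacteria-consensus-style
synthetic stand-in and is configurable.

## Module calling

A candidate module is the span from the first base of one detected site to
the last base of the *next* detected site along the replicon — i.e. the span
**includes both flanking 28-bp sites**. This inclusive convention is forced
by the coordinate arithmetic of published module lengths (a 2363397–2364617
chromosomal span corresponds to the quoted 1221-bp module length only when
both sites are counted). Pairing is consecutive-only: modules are bounded by
adjacent sites, and all-pairs pairing would double-count nested spans. On a
circular replicon the pair wrapping the origin is also considered.

Candidates longer than `max_len` (default 20,000 bp — the largest published
module is 3011 bp, so this leaves ample headroom for multi-gene cargo) are
dropped. With `require_orf = TRUE` (default) a candidate must contain a
cargo ORF of at least `orf_min_len` (default 150 bp; the smallest annotated
cargo ORF is 198 bp). A cargo ORF must overlap the inter-site interior by at
least `orf_min_len` bp rather than lie wholly inside it: the permissive
GTG/TTG start codons mean a genuine cargo ORF's 5' end can extend into a
flanking site (the reference site's central region itself contains a GTG),
and requiring containment would silently drop such modules. The flanking
sites' orientations are recorded but **not** constrained: published modules
show mixed CD/DC arrangements.

ORFs are found by a 6-frame codon scan (starts ATG/GTG/TTG, stops
TAA/TAG/TGA, longest-per-stop), which is permissive by design — cargo
annotation is delegated to the catalog step.

Cargo labelling aligns each catalog gene against the module sequence (local
alignment, orientation-normalised) and accepts matches at ≥ 0.90 identity
over the gene length; matched names are joined in coordinate order and
suffixed `_dif`. The packaged catalog
(`inst/extdata/cargo_catalog_synthetic.fa`) contains **synthetic stand-in
ORFs** with the lengths of the known dif-module cargo genes (*terC* 978 bp,
*ohr* 429 bp, *ohrR* 432 bp, *sulP* 1455 bp, *kup* 1878 bp, toxin/antitoxin
297/291 bp, …); for real-data work a catalog of real gene sequences should
be supplied.

On "at least two different p*dif* sites": we interpret "different" as *two
occurrences* (any two detected sites), since requiring different sequences
or orientations would silently discard genuine modules bounded by
near-identical sites; users can filter the output on the recorded site
sequences if a stricter reading is wanted.

## Mobility assessment

The mobility criterion is: the same module (global-alignment identity ≥
**0.98**, orientation-normalised), found on **different replicons**, in
**different sequence contexts**. Context is compared over `flank_len` =
500 bp of sequence immediately outside the module span (wrapped on circular
replicons, truncated at contig ends); two occurrences are in different
contexts when the best flank pairing — direct or inverted — stays below
**0.80** identity. Flanks shorter than 100 bp on both sides of an occurrence
are treated as uninformative and the pair is excluded rather than counted as
support. A species difference is recorded for every supporting pair but not
required by default (species labels are routinely absent on contigs); a
`strict` mode enforces it.

Before assessment, occurrences are grouped into families by single-linkage
at module identity ≥ 0.95. This threshold deliberately straddles the
published treatment of 96%-identical module variants (sometimes "the same",
sometimes named as separate variants); we group them and let the stricter
0.98 pairwise requirement decide mobility support. Pairwise alignment at
scale is guarded by two exact prescreens (length ratio, and 12-mer
containment with a proven safety margin at the 0.95 threshold), which only
skip pairs that provably cannot reach the threshold.

Tightening any threshold can only remove support — mobility can flip from
true to false but never the reverse, a property covered by tests.

## Site clustering and profiles

Clustering is single-linkage transitive closure of pairwise ungapped
identity at **0.95**, emulating the neighbour-based behaviour of classical
identity-threshold clustering tools. At 28 bp this admits at most one
mismatch per link (27/28 ≈ 0.964, 26/28 ≈ 0.929), so clusters are
one-mismatch neighbourhoods closed under chaining. DC-oriented sites are
reverse-complemented into site-intrinsic orientation first, so a site and
its reverse-complement occurrence co-cluster; CD and DC sites are clustered
together (the natural choice once orientation is normalised — clustering
them separately would split identical sequences by strand accident).
Clusters are numbered by decreasing size with deterministic tie-breaks, and
`sort_by_cluster()` writes the cluster-ordered annotated FASTA used for
visual inspection.

Per-position profiles count A/C/G/T at each of the 28 site-intrinsic
positions (sites with `N` at a position are dropped from that position's
denominator). Information content is `2 − H` bits per position. No
small-sample correction is applied by default — at the group sizes this
analysis deals in (tens to low hundreds of sites) the correction is a few
hundredths of a bit — but the standard correction `3/(2·ln2·n)` can be
switched on. Group comparison uses per-position Jensen–Shannon divergence
(base 2, bounded in [0, 1], symmetric), summarised per region (XerC arm =
positions 1–11, central = 12–17, XerD arm = 18–28). `conservation_ranking()`
checks the ordering expected of genuine *dif* sites: XerD arm ≥ XerC arm ≥
central region in mean information content. No significance testing is
attached to profile differences — none is defined for this analysis — so
`compare_profiles()` reports effect sizes only.

## The synthetic-replicon generator

The generator emulates the statistical structure the analysis assumes, with
defaults fixed once to the study conditions:

* **replicon lengths**: log-uniform on 2–400 kb (the plasmid size range
  analysed; log-uniform because plasmid collections are dense in small
  replicons and sparse in megaplasmids);
* **background**: i.i.d. nucleotides at 40% GC (the genus is AT-rich);
* **site burden**: per-replicon standalone site counts drawn from the
  observed collection-level proportions — 40% zero, 43% with 1–4, 10% with
  5–8, 7% with more than 8;
* **sub-6-kb rule**: very small plasmids carry no sites; the category is
  drawn first and the length conditionally (site-bearing replicons from
  6–400 kb), preserving both the category proportions and the size rule;
* **site divergence**: uniform 0–3 mismatches from the reference (all
  within the detection threshold), realised as exact substitution counts;
* **modules**: templates built from the cargo catalog with the published
  total spans (768–3011 bp), flanked CD…DC; a configurable number of
  *transfer events* place a second, ~0.5%-mutated copy of a template on a
  different replicon — fresh random background automatically provides the
  "different context" — while *resident* templates are placed once as
  immobile controls;
* **spacing**: planted features keep ≥ 28 bp apart so overlap resolution is
  exercised only by dedicated fixtures.

What the generator does **not** emulate: repeats and IS elements, gene
islands, compositional heterogeneity, assembly artefacts, or any
evolutionary process. Passing recovery tests on this background therefore
demonstrates correctness of the detection and bookkeeping machinery — exact
coordinate recovery, threshold behaviour, mobility logic — not robustness to
the repeat structure of real genomes, where local alignment context and IS
interruptions can complicate module boundaries.

Everything is deterministic given the spec seed; identical seeds produce
byte-identical output files.

## Numerical choices and degenerate inputs

* Identity thresholds compare match *counts* (`m ≥ ⌈28·t − ε⌉`), so 21/28
  at `t = 0.75` is inclusive and floating-point noise cannot flip a call.
* Ties in overlap resolution: identity, then leftmost, then CD before DC.
* `classify_chromosomal_sites()` breaks equal-identity *dif1* ties by lowest
  start coordinate; if no site reaches the configurable *dif1* minimum
  identity the main site is reported absent with a warning.
* Replicons shorter than 28 bp scan to an empty result (not an error);
  empty site tables propagate as empty outputs with headers.
* A module wrapping a circular origin keeps `end > length`; GFF3 export
  splits it into two parent segments sharing one feature ID (the standard
  discontinuous-feature convention).
* Global-alignment identity is matches / alignment columns with scores
  match +1, mismatch −1, gap open 5, gap extend 2; for equal-length
  substitution-only pairs this reduces exactly to Hamming identity.

## Problem sizes used in the tests

The shipped test-suite and acceptance runs use datasets scaled for a
single-CPU desk run: the end-to-end recovery check generates 50 replicons
(≈ 3–4 Mb of sequence) under the default spec; the multi-seed recovery
property uses five 10-replicon datasets; the clustering oracle uses 200
sites per seed; the category-proportion check draws 1,000 replicons with a
reduced length range (length does not enter the category draw). These sizes
were chosen to exercise every code path with comfortably measurable
statistics.

## Known limitations

* Site detection is consensus-based, not probabilistic; a position-weight
  model could rank marginal hits better but would depart from the published
  identity-threshold rule (and is deliberately out of scope).
* At the published 0.75 threshold, marginal chance hits (~1 per Mb) are
  expected on any background; downstream steps tolerate them, but a chance
  hit falling inside a genuine module would split it into two candidates.
* Cargo labelling is nucleotide-level catalog matching only — no protein
  domain annotation, and IS elements adjacent to modules are not detected.
* The mobility criterion detects *evidence of* transfer, not direction or
  mechanism; nested or overlapping module architectures are not resolved.
* GenBank parsing is minimal (LOCUS topology, DEFINITION, ORIGIN); rich
  feature tables are ignored.
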