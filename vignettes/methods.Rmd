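---
title: "Methods: genome-wide P450 family expansion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide P450 family expansion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypfam)
```

# The scientific problem

Wood-decaying basidiomycete fungi carry unusually large complements of
cytochrome P450 monooxygenases (P450s, "CYPs"), heme-thiolate enzymes
involved in the oxidation of plant material and plant defence chemicals. A
family that has accumulated many more members than its peers is a candidate
for having been under positive selection, and the mechanism behind such
expansions — repeated, often tandem, gene duplication — leaves recognisable
genomic fingerprints: many same-family genes co-located on a scaffold,
near-identical exon-intron structures among the copies, and species-specific
clades in the family phylogeny.

`cypfam` implements that analysis chain as a reusable, tested pipeline:

1. **Authentication** — keep only proteins carrying both P450 signature
   motifs.
2. **Census and enrichment** — count authentic P450s per species and family
   and flag families whose total reaches a fractional cutoff.
3. **Phylogenetics** — a minimum evolution (ME) tree per enriched family
   from Poisson-corrected protein distances.
4. **Gene structure** — exon-intron profiles, paralog clusters, and
   cross-species ortholog candidates.
5. **Tandem arrays and intron summaries** — scaffold co-location and
   per-family intron statistics.
6. **Synthetic data** — a seeded generator of multi-species complements
   with planted truth labels, so every stage can be validated without any
   genome download.

# Authentication by signature motifs

An authentic P450 must contain the heme-binding decapeptide `FXXGXXXCXG`
(the `C` is the axial cysteine ligand of the heme iron) and, upstream of
it, the `EXXR` salt-bridge motif of the K-helix. `scan_motifs()` reports
every (possibly overlapping) match of both patterns; a protein is authentic
when at least one `EXXR` start lies strictly before at least one
heme-motif start, reflecting the invariant K-helix-before-heme-ligand order
of the P450 fold.

Two decisions needed to be made here:

* **Wildcard positions and the ambiguity code.** The `X` positions of the
  patterns accept any of the 20 standard residues but *not* the ambiguity
  code `X`: an unknown residue cannot positively evidence a motif.
* **Order and multiplicity.** Both motifs may occur several times;
  requiring only one upstream `EXXR`/downstream heme pair keeps the rule
  robust to chance extra matches (a random 450-residue protein contains an
  incidental `EXXR` roughly once).

Sequences are uppercased and terminal stop characters stripped on ingest.
No minimum protein length is imposed at this stage — the 400-residue filter
belongs to the intron summaries only. Rejections carry one machine-readable
reason (`bad-sequence`, `missing-heme`, `missing-exxr`, `wrong-order`);
when both motifs are absent the reason is `missing-heme`, the primary P450
signature.

# Census and the enrichment cutoff

`build_census()` tabulates authentic records by species and CYP family
(families keyed by the family string only, e.g. `CYP5144`; subfamily-level
tables are derivable from `parse_cyp_name()` but play no role in
enrichment). `enrich()` flags a family as enriched when its summed count
reaches

\[ \mathrm{cutoff} = \mathrm{round\,half\,up}(f \cdot N), \qquad f = 0.02
\text{ by default,} \]

where \(N\) is the grand total. Round-half-up was chosen because the
source analysis quotes "2%" of 1061 proteins as "about 21"
(\(0.02 \times 1061 = 21.22\)); half-up rounding is direction-stable and
reproduces 21. For tiny totals the cutoff is floored at 1 so that it stays
a positive count. An enriched family present in at most `k_species_specific`
(default 2) species is additionally flagged *species-specific*; the default
of 2 reproduces the two species-specific calls of the motivating six-genome
study (one family in one species, one in two).

# Minimum evolution phylogenetics

The tree stage deliberately re-implements the classical distance pipeline
so that its behaviour is fully specified and testable:

* **p-distance** (`p_distance_matrix()`) — proportion of differing
  residues. Under *complete deletion* (the default, as in common
  implementations) every column gapped in any taxon is removed globally
  before any pair is compared; *pairwise deletion* is available by flag.
* **Poisson correction** (`poisson_distance()`) —
  \(d = -\ln(1 - p)\), expected substitutions per site under equal rates
  across sites. \(p \ge 1\) is an error; \(p > 0.95\) is capped at
  \(-\ln(0.05)\) with a warning, keeping matrices finite without silently
  distorting typical inputs.
* **Neighbor joining** (`nj_tree()`) — standard Saitou–Nei agglomeration
  on the Q-criterion. Ties are broken by the smallest (i, j) index pair in
  the current node ordering (original taxa first, joined nodes appended),
  so results are fully deterministic.
* **OLS branch lengths** (`ols_branch_lengths()`) — lengths minimising
  \(\sum_{i<j} (d_{ij} - \mathrm{path}_{ij})^2\). The ME score is the *raw*
  sum of fitted lengths, negatives included — the scoring criterion and the
  presentation serve different contracts, so negative lengths are clamped
  to zero only in emitted Newick strings.
* **CNI search** (`cni_search()`) — iterated best-improvement search over
  all topologies within `level` nearest-neighbor interchanges (level 1,
  the default, is the plain NNI neighborhood of \(2(n-3)\) topologies); a
  neighbor is accepted only if its ME score improves the current one by
  more than \(10^{-12}\). The "search level" semantics of legacy GUI
  software are not documented publicly; the NNI-radius interpretation is
  recorded here as this package's definition.
* **Exhaustive oracle** (`exhaustive_me()`) — enumerates all
  \((2n-5)!!\) topologies (feasible to \(n = 8\)), with ties broken by the
  lexicographically smallest canonical topology string. It exists to
  certify the heuristic: on additive matrices CNI-from-NJ must (and in the
  test suite does, in 100/100 cases) return the same topology.

`family_tree()` chains the five steps. Degenerate inputs behave
predictably: two members give the single-edge tree (score = the pairwise
distance), identical sequences give a star with zero lengths.

**Problem sizes.** The bundled analysis applies CNI to families with at
most 50 members and reports NJ + OLS beyond that. Each CNI sweep refits
OLS for every NNI neighbor, so the cost grows roughly with
\(n^5\) per sweep, while NJ alone is already exact on near-additive data;
50 taxa keeps a full six-genome run comfortable on a single core while
still refining every family where the search can plausibly change the
topology.

# Gene structure, paralogs, orthologs

Structure profiles (`structure_profile()`) are exon-length vectors in
transcript orientation (minus-strand genes reversed), derived from CDS
features when an mRNA has any, else from exon features — never mixing the
two, which removes UTR-annotation ambiguity deterministically. GFF3
coordinates (1-based inclusive) are converted to 0-based half-open
internally; round-trip tests cover the conversion. When a protein length
is supplied, the internal consistency check
\(\sum \text{CDS lengths} = 3L + 3\) warns (never errors) on mismatch,
since public gene models are imperfect.

The published analysis matched structures visually ("exons of the same
size align together"); the package replaces that with an explicit rule:
two genes share a structure iff they have the same intron count and the
fraction of positionally paired exons whose lengths differ by at most
`tol_nt` (default 3 nt — one codon, the smallest tolerance that survives
codon-boundary annotation wobble) reaches `theta` (default 0.8). The score
is symmetric, 1 on self, and gated to 0 across different intron counts.

* `cluster_paralogs()` — single-linkage components of the same-structure
  graph among one species' family members; components of size ≥ 2 are
  duplicate groups.
* `ortholog_candidates()` — all cross-species same-structure pairs of a
  family; many-to-one mappings are intentionally allowed (one gene in
  species A may match an entire duplicate cluster in species B — the
  single-ortholog-duplicated-eightfold pattern).
* `intron_summary()` — min-max intron counts and the P/I statistic (P =
  genes sharing the modal intron count I) over proteins of at least 400
  residues; ties on the mode list every tied count and report P/I for the
  smallest. Cells with no qualifying gene are reported `NA`, as in the
  published table.

Scaffold-level duplicate counts in the motivating paper mix tandem and
structural evidence in a way that is not fully specified, so the package
reports structural clusters and scaffold distributions separately and does
not claim to reproduce those exact counts.

# Tandem arrays

`detect_tandem()` follows the published scaffold-level criterion by
default: two or more same-family, same-species genes on one scaffold form
an array, regardless of intervening genes, and strand is ignored. A finite
`max_intervening` tightens this to adjacency runs for users who want
stricter tandem semantics. `scaffold_distribution()` reproduces the
scaffolds-with-counts presentation (singletons included, descending
count).

# The synthetic generator

`synthetic_genomes()` emulates the *statistical* structure of a
multi-genome P450 complement; it is bookkeeping-level, not a sequence
evolution simulator:

* **Planted counts.** The default species-by-family matrix
  (`default_family_counts()`) has six species and twelve families totalling
  303 genes: four broadly expanded families (88, 72, 60, 40 members), one
  single-species expanded family (36), and eight rare single-member
  families. With the 2% rule the planted cutoff is 6, so expanded families
  clear it by ≥ 5 counts and rare families sit ≥ 5 below — margins wide
  enough that pseudogene ablation (apportioned across families by largest
  remainder, hence proportional) can never flip a call.
* **Divergence.** A duplicate's protein differs from its parent by
  independent per-site substitution with probability \(1 - e^{-\mu}\)
  (default \(\mu = 0.05\) substitutions/site, a recent-duplication scale).
  The six motif anchor residues are exempt — purifying selection on the
  signature motifs — so authentic genes remain authentic; the expected
  observable p-distance is therefore \((1 - 6/L)(1 - e^{-\mu})\), which the
  calibration test verifies within three standard errors. Divergence is
  substitution-only (no indels), so family members stay equal-length and
  the raw sequences are a valid ungapped alignment — alignment construction
  is intentionally out of scope.
* **Orthologs.** Half of the multi-species families (default
  `ortholog_fraction = 0.5`) are seeded before the species split: one
  ancestor, whose exon structure is copied into every species, making the
  founders cross-species structural orthologs. The rest are founded
  independently per species (same protein length, own structure).
* **Tandem placement.** A duplicate lands downstream on its parent's
  scaffold with probability `p_tandem = 0.8` (2 kb intergenic spacing,
  60 nt introns), else on a fresh scaffold — mirroring the predominance of
  tandem arrangements in the real genomes.
* **Structural jitter.** At `jitter_nt = 0` (default) duplicates copy the
  founder's exon structure exactly. With `jitter_nt > 0`, each exon of a
  duplicate is perturbed with probability `jitter_prob = 0.2` by a uniform
  nonzero amount up to ±`jitter_nt`. The occasional-wobble model reflects
  how annotated paralogs actually differ — most exon boundaries agree
  exactly, a minority wobble by a few nucleotides — rather than jittering
  every boundary of every copy.
* **Pseudogenes.** `round(pseudo_fraction * total)` genes (default 10%)
  have their motifs ablated. Because incidental `EXXR` matches are common
  in random sequence, ablation loops until `scan_motifs()` reports
  non-authentic, guaranteeing that the authentication stage rejects
  *exactly* the planted pseudogene set.

Identical seed and configuration give byte-identical outputs (FASTA, GFF3,
names table, truth JSON).

**What passing tests do and do not show.** The generator gives exact truth
labels for counts, clusters, arrays and pseudogenes, so recovery tests are
sharp; but it does not model indels, intron gain/loss, alignment error,
fragmented assemblies, or mis-annotated gene models. Perfect recovery on
synthetic data therefore validates the pipeline's logic, not its robustness
to the full messiness of real genome annotations — on real data the
structure-matching tolerance and the saturation cap are the knobs that
absorb part of that messiness.

# Numerical choices, degenerate inputs, limitations

* Round-half-up for the cutoff (see above); cutoff floored at 1.
* NJ ties by smallest index pair; topology enumeration order fixed by
  sequential leaf insertion; exhaustive ties by canonical topology string —
  all deterministic and documented for reproducibility.
* OLS uses the normal equations with a pseudoinverse fallback for
  (non-generic) singular designs; an all-zero distance matrix yields all
  zero lengths.
* Saturated distance pairs (p > 0.95) warn and cap rather than error;
  p = 1 errors.
* Two-taxon trees are represented as two half-length pendant edges (the
  underlying `phylo` structure has no single-edge tree); the ME score is
  still the full pairwise distance.
* The published per-genome totals cannot be reproduced without the
  original sequence sets (the source supplement is not machine-readable),
  and the published tree figures depend on undeposited alignments; the
  package reports its own counts and trees and validates the machinery by
  oracle and recovery tests instead.

# Reproducing the bundled analysis

The numbered scripts under `analysis/` run the whole chain on the default
synthetic complement (seed 1) and write their tables under `results/`;
`scripts/acceptance.R --seed <s> --out <path>` recomputes the headline
quantities from scratch. Both touch only functions exported by the
package, so the test suite (`testthat::test_dir("tests/testthat")`) is the
authoritative specification of every behaviour described here.
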