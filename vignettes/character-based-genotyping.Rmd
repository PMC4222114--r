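---
title: "Character-based SNP genotyping for cultivar identity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character-based SNP genotyping for cultivar identity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitisnp)
```

## The problem

Clonally propagated crops such as grapevine accumulate thousands of named
cultivars whose identities blur over centuries of exchange: the same
genotype circulates under several names (synonymy), one name covers
genetically distinct material (homonymy), and nursery labeling mistakes
propagate silently. Distance-based barcoding collapses below the species
level because within-species divergence is tiny, so identity work at the
cultivar level uses a *character-based* approach instead: every single
nucleotide polymorphism in a panel of single-copy nuclear amplicons is a
character, and a cultivar is identified by its exact combination of
character states.

The data tier this package works on is the curated Sanger consensus: one
sequence per accession per amplicon, pre-aligned, in which a heterozygous
position of the diploid genome is recorded as the two-base IUPAC code
(R, Y, S, W, K, M). Nothing is phased; the unit of identity is the
unphased diploid *genotype string*, not a haplotype. Because these crops
are propagated by cuttings, recombination within a cultivar is
negligible and the genotype string is effectively fixed, which is what
makes exact string matching a sound identity criterion.

## Pipeline model

1. **Site classification** (`classify_columns`, `discover_snps`). For a
   chosen accession scope, every alignment column is assigned to exactly
   one of four classes: *indel* (any `-`), *ambiguous* (any `N` or a
   three-base code, which a diploid consensus cannot legitimately
   produce; a gap takes precedence), *snp* (the union of IUPAC-expanded
   states holds two or more bases) or *monomorphic*. The four counts
   always sum to the aligned length, which the audit table makes
   checkable. Exclusion is deliberately conservative and scope-wide: one
   ambiguous call in one selected accession removes the column for that
   comparison, so no imputation ever happens. A minor-allele-frequency
   filter (most common allele < 0.95) exists but is off by default:
   cultivar panels are curated collections, not population samples, so
   every variable site is informative. Sites failing the filter are
   tallied as monomorphic so the audit identity still holds.

2. **Genotype reconstruction** (`build_genotype_matrix`,
   `collapse_genotypes`). One character per valid SNP site per accession,
   concatenated in fixed marker order then ascending position.
   Homozygous and heterozygous states are *different* characters: `A`
   and `R` differ even though they share an allele. Accessions are
   partitioned by exact string equality; group ids are assigned by
   descending size, ties by first appearance. The group count is the
   genotype number (Hn), group sizes the per-genotype accession counts
   (Nh). Because SNP validity depends on the accession scope, the
   genotype matrix for a sub-scope must be rebuilt from sites re-filtered
   for that scope; the pipeline does this automatically.

3. **Diagnostic keys** (`diagnose_group`). A *characteristic attribute*
   (CA) for a group is a set of (site, state) pairs carried by every
   member and by no outsider ("pure" diagnostics). Single-site CAs
   ("pure-simple") are found by a direct scan. When none exist, minimal
   multi-site ("compound") CAs are found by exhaustive subset search up
   to `max_exhaustive` sites (default 3; sizes 2 and 3 use a co-match
   cross-product so the search is quadratic in sites, not combinatorial).
   Beyond the cap a greedy set cover over the outsiders runs, followed by
   subset-deletion pruning and a budgeted exact pass over the
   cardinalities between the cap and the greedy solution, so on small
   instances the emitted CA is always a true minimum and on large ones it
   is at least minimal (no proper subset is diagnostic). Ties are broken
   by smaller cardinality, then site order. Every emitted CA can be
   re-verified against the raw matrix with `check_ca`.

4. **Naming report** (`naming_report`, `one_off_pairs`). Synonymy
   candidates are groups carrying two or more cultivar names; homonymy
   candidates are names split across groups (this is also how a mislabel
   surfaces); clone checks flag replicated cultivars whose accessions do
   not co-group. Groups differing at exactly one site are reported
   separately: a one-off pair is the signature of a derived clone or a
   parent-offspring relationship, not of independent material.

5. **Distances and tree** (`k2p_distance`, `nj_tree`,
   `bootstrap_supports`). Kimura two-parameter distances are computed on
   fixed bases only: any site where either sequence is not a plain
   A/C/G/T is deleted pairwise, including heterozygote codes - K2P has
   no defined meaning on a base mixture, and this matches common
   distance-software behavior. With transition proportion P and
   transversion proportion Q, d = -(1/2)ln(1-2P-Q) - (1/4)ln(1-2Q).
   Saturated pairs (non-positive log argument) and empty overlaps are
   *flagged* undefined, never silently zeroed, and `nj_tree` refuses
   matrices containing them. Neighbor-joining uses the standard
   rate-corrected Q criterion with deterministic first-minimum
   tie-breaking; negative branch-length estimates are clamped to zero
   with the deficit moved to the sibling edge so path lengths are
   preserved. Bootstrap resampling draws all alignment columns (not only
   SNP columns) with replacement; support is the percentage of valid
   replicate trees containing each internal bipartition of the point
   tree. Replicates whose resampled matrix has an undefined distance are
   dropped and counted. Every stochastic operation takes an explicit
   integer seed and is exactly reproducible.

6. **Diversity statistics** (`diversity_stats`, `diversity_table`).
   Allele counts come from 2N chromosomes (homozygote = two copies,
   heterozygote = one of each), so the reported sample size is an allele
   count, twice the number of individuals. Per locus: observed alleles
   na, effective alleles ne = 1/sum(p^2), Shannon index
   I = -sum(p ln p), Nei gene diversity H = He = 1 - sum(p^2) with no
   small-sample correction (the choice is isolated in one function),
   observed heterozygosity Ho, and Fis = 1 - Ho/He where He > 0. Table
   rows are means over all loci, monomorphic loci contributing
   na = ne = 1 and I = H = 0, except Fis, which averages only loci with
   He > 0.

## The synthetic data generator

No public sequence deposit accompanies the motivating study, so the
package carries a first-class generator (`sim_config`,
`simulate_dataset`) whose defaults emulate the study panel: five markers
of 761/419/418/800/919 bp (3317 bp total), 150 cultivars in eight
geographic subgroups, six cultivars with clonal replicates (copies
2, 2, 3, 2, 2, 2), three synonym pairs, one mislabel, five outgroup
species, segregating sites at 1 SNP per 34.5 bp, and heterozygosity
0.3 at a segregating site. Every planted fact - the genotype partition,
synonym pairs, mislabels, per-site diploid states, outgroup membership -
is returned as machine-checkable ground truth.

Design points worth knowing:

* **Consensus-level simulation.** The analyzed tier is the curated
  consensus, so there is no read-level error model; base-calling failure
  is modeled only as planted `N` columns (and indels as planted `-`
  columns), both off by default.
* **Independent sites.** Sites are independent characters; no linkage or
  recombination model. For vegetatively propagated material within-
  cultivar recombination is negligible, and the analysis itself treats
  sites as characters.
* **Outgroup geometry.** Outgroups evolve from a shared outgroup
  ancestor placed at half the configured divergence from the ingroup
  ancestor, then radiate a further half each, under a Poisson
  substitution process with a 2:1 transition:transversion bias. This
  puts both the outgroup-vs-ingroup and the outgroup-vs-outgroup mean
  K2P near the configured divergence (matching the observed pattern in
  the motivating panel, where both sit near 0.21) and gives the
  ingroup/outgroup split a long shared internal edge, so bootstrap
  support for the basal split is a meaningful target. The transition
  bias makes K2P differ from the raw p-distance, so the correction is
  actually exercised by tests.
* **Balanced allele frequencies.** At a segregating site the non-het
  probability mass is split equally between the two homozygotes, so
  ingroup allele frequencies sit near 0.5 and per-locus diversity is
  near its biallelic maximum (H about 0.5). Real panels have skewed
  frequency spectra and much lower mean H (0.1-0.2); recovery tests are
  unaffected, but simulated diversity tables should not be read as
  calibrated to real germplasm.
* **Distinctness guard.** Distinct genotype ids are guaranteed distinct
  state vectors: colliding genotypes (possible in tiny test
  configurations) are redrawn deterministically on the seeded stream,
  and configurations with fewer than log3(genotypes) segregating sites
  are refused rather than silently mislabeled.

What passing the recovery tests shows - and does not show. Exact
partition recovery (adjusted Rand index 1.0 across seeds) demonstrates
that the discovery-to-collapse path is lossless under the generator's
assumptions: clean diploid consensus calls, no missing amplicons, no
alignment error. It does not certify performance on real chromatograms,
where base-calling quality, allele dropout and alignment choices
dominate; those steps are upstream of this package by design.

## Numerical and interface choices

* Positions are 0-based internally, half-open ranges; all reports are
  1-based (`marker:pos`).
* Sequences are uppercased and `U` is normalized to `T` at load; the
  load alphabet is the full 16-symbol IUPAC set so that three-base codes
  can be screened rather than rejected at the door.
* bp-per-SNP densities round half-up to two decimals, matching the
  printed convention of the field (base R `round` rounds half to even).
  One published per-marker density cell (IIC08, 24.54) is inconsistent
  with its own printed inputs (418/17 = 24.59); the package reproduces
  the arithmetic, not the typo.
* Trees are `ape::phylo` objects; Newick output writes supports as
  internal node labels and branch lengths with 10 significant digits.
* `run_pipeline` writes every output as delimited text or Newick plus a
  checksummed manifest; identical config and seed give an identical
  manifest, which the test suite verifies by double-running.

## Problem sizes used by the test suite

The suite regenerates all fixtures in code. The heavier checks use: ten
default-size panels (about 163 accessions by 3317 bp) for partition
recovery, twenty for the SNP-count calibration band, 1000 random pairs
for the K2P oracle, 200 random additive matrices (4-8 taxa) for NJ
exactness, 200 random small instances (up to 8 accessions by 10 sites)
for the CA oracle against brute force, and ten 9-taxon, 200-column
panels with 100 bootstrap replicates for the split-support check. The
whole suite runs in about a minute on one core.

## Known limitations

* Pedigree inference is out of scope: a handful of amplicon SNPs cannot
  separate parent-offspring from clonal identity, and the one-off-pair
  report is the honest extent of what the data support.
* Somatic berry-colour chimeras (the Pinot problem) are invisible to any
  marker set that does not tag the causal locus; identical genotype
  strings there mean "indistinguishable at these markers", not "the same
  cultivar".
* K2P deletes heterozygote codes pairwise, so distance-based summaries
  use slightly fewer sites between highly heterozygous accessions; the
  character-based path is unaffected.
* `He` carries no small-sample correction; with very few individuals per
  subgroup the expected heterozygosity is biased upward relative to
  corrected estimators.
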