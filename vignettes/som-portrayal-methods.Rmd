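---
title: "SOM portrayal of population SNP data: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SOM portrayal of population SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical machinery inside `sompop`, the
assumptions it rests on, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where the method leaves room.

## 1. The model

### Allele coding

Genotypes of biallelic SNPs are coded per individual as the count of
minor-allele copies: 0 (homozygous major), 1 (heterozygous), 2
(homozygous minor). The minor allele of each SNP is decided **once over
the merged sample of all individuals**, not per population: a
per-population orientation would make the same genotype mean different
things in different columns and destroy cross-population comparability of
profiles. When the alternate allele's global frequency is exactly 0.5 the
alternate allele is designated minor, deterministically. The resulting
N × M matrix satisfies `maf = rowSums(scores) / (2 * M)` by construction,
with `maf` in [0, 0.5].

One consequence worth knowing: a column subset of a coded matrix (used by
the zoom-in) keeps the *global* orientation, so subset frequencies may
exceed 0.5. That is intended — the zoom-in compares the same alleles as
the worldwide map.

### Batch SOM on centered profiles

Each SNP is a data point: its profile is the length-M vector of scores.
Profiles are feature-centralized (per-SNP mean subtracted) so the map
organizes by profile *shape* (which populations carry the minor allele)
rather than by absolute MAF. The SOM has `rows × cols` prototypes
("meta-SNPs") on a rectangular grid; training is **batch**: per epoch,
(1) every SNP is assigned to its Euclidean best-matching unit (BMU; ties
to the lowest unit index), (2) every prototype is replaced by the
neighborhood-weighted mean of all profiles, with Gaussian weights
`exp(-d²/2σ²)` on grid distance and a radius σ decaying linearly from
`max(rows, cols)/2` to 1 over the epochs. Batch updating makes training
deterministic given the initialization; the default initialization is
itself deterministic (prototypes laid along the two leading principal
directions of the data, spanning ±2 SD), so the default fit needs no
seed. Random initialization (prototypes sampled from the data rows) is
available for robustness checks and requires a seed.

As the radius vanishes the update becomes the batch k-means fixed point
(each prototype the centroid of its members) — a property the unit tests
check exactly on tiny instances. The final stored assignment is always a
fresh nearest-prototype pass.

### Portraits, summary map, spots

Portraits are drawn on the **raw 0–2 score scale**, not the centered
training scale, so that red literally means minor-allele enrichment; the
centered representation is an internal training detail (both exports are
available). A unit's value for an individual is the mean raw score of its
member SNPs; units without members are filled by the iterated mean of
their 8-neighbors, which produces contiguous images without inventing
structure away from observed units. Group portraits are element-wise
means; difference portraits are element-wise differences on a symmetric
[-2, 2] scale.

The summary map takes the per-unit **maximum over group mean portraits**
(a unit is interesting if hot in *some* population). Maxima over
individuals were rejected as noise-prone. Segmentation keeps units
strictly above a quantile of the summary map (default 0.90), forms
8-connected components, discards components below `min_units` (default
5), and labels the survivors A, B, … by decreasing peak value. Both
segmentation parameters are configuration keys, not constants: the
method does not dictate particular segmentation thresholds, so they are
surfaced rather than hard-coded as fixed truths.

### Enrichment

For each spot and each level-3 disease term, a one-sided Fisher's exact
test (alternative "greater") on the 2 × 2 table in-spot/out-spot ×
annotated/other, with the **universe = all SNPs clustered on the map**
(not the genome, not the full catalog): the null hypothesis is a random
distribution of the clustered SNPs among the spots. A SNP counts once per
term regardless of how many source databases report the pair. Raw p is
the primary column (spot-enrichment tables in this field are commonly
reported uncorrected); a Benjamini–Hochberg column over all reported
tests is always emitted for rigor. Gene-set (GO-style) over-representation is the same
machinery with gene→set annotations substituted for SNP→disease ones.

### Ontology level mapping

Disease vocabularies are harmonized at "level 3": a term's level is its
**minimum is_a-depth from the ontology root** (breadth-first; the root is
level 0). Terms deeper than 3 map to *all* of their level-3 ancestors —
dropping ancestors would silently lose associations, and contingency
counts are per-term anyway. Terms shallower than level 3 are kept as-is
and flagged `shallow` rather than being guessed into level 3; unknown or
root-unreachable terms are flagged `unmapped`, never fatal. Minimum depth
is the deterministic resolution of the occasional multiple parentage in
real disease ontologies.

### Similarity mapping

Individuals are compared by Pearson correlation between their
**portrait vectors** (length K, the meta-SNP level) — not raw SNP
vectors — and connected by a minimum spanning tree on dissimilarity
`1 − r`. The transform is `1 − r` rather than `1 − |r|`: anti-correlated
individuals are genuinely distant here. Kruskal's algorithm with a stable
sort on (weight, node pair) makes the tree deterministic under ties.

## 2. Parameters that matter

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `max_missing_rate` | 0 | fraction | complete-case matrix; any missing call removes the SNP |
| `maf_threshold` | 0.05 | frequency | strict inequality: MAF = 0.05 is removed |
| `rows`, `cols` | 55 × 55 | grid units | K = 3,025 meta-SNPs, the standard worldwide geometry |
| `epochs` | 100 | sweeps | fixed budget with logged quantization error, no stopping rule |
| `radius_start`, `radius_end` | max(rows,cols)/2 → 1 | grid units | linear decay, Gaussian kernel |
| `threshold_quantile` | 0.90 | quantile | foreground = top decile of summary values |
| `min_units` | 5 | units | discard speckle components |
| ternary cuts | 2/3, 4/3 | score | equal thirds of the 0–2 range |

## 3. The synthetic world

`generate_panel()` emulates a multi-population genotype panel under the
**Balding–Nichols** model: each background SNP draws an ancestral
frequency p uniformly from `ancestral_maf_range` (default (0.05, 0.5],
the spectrum of an array panel already screened at MAF > 0.05); each
population's frequency is Beta-distributed with mean p and variance
p(1−p)·Fst; genotypes are binomial(2, freq). Planted blocks override the
frequency: the block's elevated value (default 0.6) in target
populations, a 0.05 baseline elsewhere, and every block SNP is annotated
with the block's disease term. Background SNPs receive random decoy leaf
terms (by default all of them, mirroring a panel where every SNP is
disease-associated). All randomness flows from one seed through fixed
per-component sub-streams, so panels are bit-reproducible. An optional
LD knob (`add_ld_companion`) duplicates a SNP's genotypes with a flip
probability, in either orientation, to exercise the LD co-location
property.

What the generator does **not** emulate: linkage disequilibrium decay,
recombination, coalescent genealogies, ascertainment bias, genotyping
error, or sex chromosomes. A green planted-recovery test therefore
establishes that the pipeline detects *frequency-differentiated SNP
blocks above the drift noise floor* — not that it reproduces any
real-data result.

### A known limitation, documented deliberately

The default synthetic world (Fst 0.1, ancestral MAF up to 0.5, blocks at
frequency 0.6, 20 × 20 grid, q0.90 segmentation) does **not** allow clean
block recovery by Jaccard overlap: Balding–Nichols drift at Fst 0.1
routinely pushes background population frequencies past 0.6, so planted
blocks sit at the noise ceiling; and the q0.90 foreground (40 of 400
units) necessarily exceeds the ~24 units the four blocks occupy, so
adjacent co-drifted background units merge into the spots. Measured over
seeds, every planted block that surfaces is recovered with near-perfect
*recall* and the correct top enriched term, but the Jaccard index against
the exact planted set plateaus around 0.5–0.8. The strict
all-blocks-Jaccard ≥ 0.8 acceptance check is therefore left failing, with
the analysis recorded rather than the world or the threshold quietly
adjusted; the module test suite asserts the properties that do hold
(spot count, recall, top-term identity) in a low-MAF background where the
planted signal is above the drift floor.

## 4. Numerical choices

- **BMU ties** go to the lowest unit index; **spot labels** order by
  decreasing peak; **MST ties** by lexicographic node pair — every
  tie-break is deterministic so reruns are byte-identical.
- **Fisher p** is computed as the hypergeometric upper tail
  (`phyper(a − 1, …, lower.tail = FALSE)`); the test suite checks it
  against an independent `lchoose`-based enumeration to 1e-12.
- **Quantile** for segmentation is R's default type-7 sample quantile;
  the comparison is strict, so a constant map yields no foreground.
- **Empty-unit fill** iterates neighbor means until the grid is full; an
  all-empty map is an error rather than a silent zero fill.
- **Degenerate inputs**: empty VCF bodies give empty panels; multi-allelic
  and non-SNP records are skipped with a count; a sample missing from the
  metadata, a non-finite profile, a constant portrait in the correlation,
  and a cycle in the ontology are all hard, named errors.

## 5. Known limitations

- No toroidal or growing SOM variants; the rectangular 8-neighbor grid is
  the only topology.
- Blue (major-allelic) regions are rendered but not segmented.
- No genotype imputation, liftover, or ploidy handling beyond uniform
  diploidy.
- The OBO reader parses `id`, `name`, `is_a` and `is_obsolete` only —
  sufficient for level mapping, not a general ontology toolkit.
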