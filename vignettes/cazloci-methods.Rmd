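---
title: "cazloci: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cazloci: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazloci)
```

# Scope and model

`cazloci` annotates the carbohydrate-degradation machinery of binned
(meta)genomes from three inputs that any standard upstream toolchain
produces: per-genome gene models (GFF3 + protein FASTA), protein-vs-HMM
domain hits in HMMER3 `--domtblout` layout, and optionally a spectral-count
protein table from a validated metaproteome search. It does not score
profile HMMs, assemble, bin, or call genes; it starts where those tools
stop and ends with locus-level biology: CAZyme module profiles, multimodular
architectures, PUL calls, cellulosome capability, sequence novelty, and
metaproteome evidence.

# Domain-hit filtering

A domain hit is retained iff

* its per-domain independent E-value satisfies `i_evalue <= 1e-6`, and
* its model-side span covers at least 30% of the HMM:
  `(hmm_to - hmm_from + 1) / model_length >= 0.30`.

Three choices deserve comment. First, the filter uses the per-domain
i-Evalue rather than the full-sequence E-value, because the retained unit
is a domain: a multi-domain protein can carry one convincing and one
spurious hit. Second, coverage is measured on the model side (the HMM
coordinates), not the protein side — the criterion asks whether enough of
the *family model* is matched. Third, hits at exactly the cutoff are kept;
`<=` is the conventional reading of an E-value threshold, and the boundary
is config-exposed (`evalue_max`, `coverage_min`) for users who want the
stricter reading.

# Overlap resolution and architectures

Profile scans routinely produce several overlapping hits on one region.
Hits on a protein are ranked by increasing i-Evalue (ties: higher bit
score, then lexicographic model name for determinism) and accepted greedily
unless they overlap an accepted hit by more than half the shorter
alignment interval (`max_overlap_fraction = 0.5`, the dbCAN-style
convention). Survivors sorted by alignment start give the N→C architecture
string (`GH5_4-CBM22-CE3-dockerin_I`). Subfamily suffixes are preserved
verbatim everywhere: GH5_1 and GH5_4 are different strings, and the
distinct-architecture count is therefore subfamily-sensitive. Family-level
roll-ups (substrate categories, the genome heatmap matrix) strip only the
trailing subfamily token (`GH13_9 -> GH13`).

Classification rules:

* **CAZyme**: any GH/GT/CE/PL/AA/CBM domain. CBM-only proteins count as
  CAZymes (CAZy treats CBMs as associated modules) but never as
  multimodular enzymes.
* **Multimodular enzyme**: at least one GH/CE/PL catalytic domain plus at
  least one accessory module (CBM/SLH/dockerin/cohesin). GT- and AA-only
  proteins are excluded from multimodular reporting, mirroring the
  restriction of multimodularity statistics to the biomass-active classes.
* **Scaffoldin candidate**: any cohesin-bearing protein. No attempt is made
  to subtype scaffoldins; cohesin/dockerin subfamily labels are carried
  through unaltered.
* **DUF-accessory**: at least one DUF domain and one accessory module with
  no catalytic domain — the discovery shortlist for new enzyme families.

# PUL calling

The anchor is a *tandem susCD pair*: two rank-adjacent genes on one contig,
one carrying a SusC model (TIGR04056-style) and the other SusD, in either
order, strand ignored. Ranks are the 0-based ordinals of protein
predictions along a contig in coordinate order — locus geometry is measured
in gene counts, never base pairs, so the caller is insensitive to
intergenic distances. Matching is greedy left-to-right and each gene joins
at most one pair; for runs like SusC-SusD-SusC-SusD this equals the
maximal matching. Canonical order and same-strand requirements are optional
strictness flags (`strict_order`, `same_strand`), off by default because
tandem-pair biology does not require them.

Each pair spans `[min(pair) - window, max(pair) + window]` gene ranks,
clipped at contig ends, with `window = 5` (five protein predictions up- and
downstream). The window is anchored at the pair's outer boundaries rather
than at each gene separately; with a two-gene anchor the two readings
differ by at most one rank, and the boundary-anchored form is the one the
window-sensitivity tests pin down. Overlapping windows on a contig merge
transitively into one multi-anchor call — extended PULs with several susCD
pairs are a documented architecture. Calls with no CAZyme cargo are
retained and flagged `no_cazyme`: a susCD-anchored locus is a transport
locus even when its hydrolases sit elsewhere. Dockerin-bearing proteins
inside a PUL window are reported as members but never alter boundaries.

# Cellulosome capability

A genome is cellulosome-capable iff it encodes (i) at least one scaffoldin
candidate and (ii) at least one *multimodular* dockerin enzyme — a dockerin
plus a GH/CE/PL catalytic domain plus at least one further accessory
module. Plain dockerin-catalytic fusions alone do not qualify, and neither
do cohesin-only genomes; both appear in real bins and both are planted as
decoys by the generator so the rule is tested against sharp negatives.

# Sequence novelty

Each query is aligned locally (Smith–Waterman, BLOSUM62, gap open 11,
extend 1 — the classic protein database-search scoring) against every
reference; percent identity is identities over alignment columns, and the
record keeps the reference with the maximum identity. Two design points:

* **Significance floor.** Unrelated protein pairs yield short local
  alignments whose identity can exceed 50% over a dozen columns, which
  would corrupt a maximum-over-references statistic. Alignments with raw
  score below `min_score = 75` are therefore treated as no hit. The value
  was calibrated on simulated data before the test suite was written:
  unrelated 400-residue pairs score at most ~60 under this scoring, while
  genuinely homologous pairs at 50% identity score above 800, so the floor
  separates the regimes by an order of magnitude and plays the role of a
  database search's significance cutoff.
* **Strict threshold.** The novelty fraction counts records strictly below
  the threshold (default 90%), among records with a hit; queries with no
  significant hit are reported separately and never enter the denominator.

# The synthetic-data generator

`simulate_bins()` emulates the downstream products of a binned-metagenome
study: ten genomes of 200 genes by default (bins in small communities carry
roughly 1,200–4,000 genes; the default community totals ~2,000 plus an
unbinned pool), 25 planted PULs, three cellulosome loci, free-standing
multimodular CAZymes, DUF-accessory proteins, and a secreted subset with
negative-binomial spectral counts (mean 8, dispersion 1.5 — overdispersed,
as spectral counts are). Gene coordinates live on a fixed grid (1.2 kb
genes, 100 bp gaps) because locus calling uses gene order only; coordinates
exist for format fidelity.

Planted geometry is designed to make recovery tests sharp:

* every PUL holds one cargo gene at exactly the window boundary (rank
  distance 5) and one decoy CAZyme one rank beyond it (distance 6), so a
  window of 4 provably loses cargo and a window of 6 provably absorbs the
  decoy;
* decoys include isolated SusC genes, the distance-6 CAZymes, a
  cohesin-only genome and a dockerin-only genome;
* planted blocks are spaced so that windows of distinct PULs never overlap
  and background CAZymes never fall inside a window.

The hit table carries, besides the true domains, hits that fail the
E-value or coverage filter and redundant same-interval hits of a worse
E-value, so the filter and the overlap resolver are both exercised on
fixtures. Novelty queries are background CAZymes; their references are
generated by `mutate_to_identity()`, which substitutes exactly
`round(n * (1 - target))` positions, stratified along the sequence (one per
equal-width block). Stratification keeps local identity equal to global
identity, so the local aligner recovers the target to within half a point;
with end-clustered substitutions, alignment end-trimming would bias the
recovered identity upward. Real homologs, of course, contain indels and
domain-level divergence the generator does not model: passing recovery
tests shows the statistic is computed correctly, not that 400-residue
substitution-only divergence is a faithful evolutionary model.

Everything planted is recorded in a JSON truth manifest (loci with anchor
ranks and cargo ids, architectures, identities, decoy inventory), and a
fixed seed reproduces every file byte-for-byte.

# Metaproteome integration

The spectral table is taken as already validated (protein-level FDR
filtering happens in the search platform upstream); counts are used raw,
without NSAF-style normalization. A bifunctional protein (e.g.
`GH5_4-CBM22-CE3-dockerin_I`, both cellulase and hemicellulase chemistry)
contributes its full spectral count to every substrate category it matches
— category totals are then not a partition of the input sum — and a second,
disambiguated total splitting the count equally across categories is
reported alongside. Detected proteins missing from the annotation are
totalled as unannotated rather than dropped, so the input spectral sum is
always conserved and checkable. Substrate categories come from a fixed
family→category map seeded with the classic groupings (cellulases GH5,
GH9, GH30, GH51, GH74, GH94; amylases GH13, GH77; oligosaccharide-degrading
GH1/2/3/29/31/35/36/38/39/42/97; hemicellulases and pectinases likewise);
GH97 is placed with the oligosaccharide-degrading enzymes, the assignment
consistent with multi-family PUL cargo compositions, though some of the
literature groups it with amylases. Unknown families map to "other".

# Numerical and degenerate-input choices

* All coordinates are 1-based inclusive (HMMER/GFF3 convention); ranks are
  0-based ordinals.
* Ties in overlap resolution break by bit score then model name; all
  orderings in reports are lexicographic, so outputs are byte-stable and
  diffable, and the end-to-end pipeline is hash-identical across runs.
* Empty inputs return typed empty objects, never errors: an empty hit
  table yields an empty architecture set, a pairless contig yields zero
  PUL calls, an empty spectral table yields zero totals. A zero-CAZyme
  community makes the binned fraction undefined (`NA`), not zero.
* Errors are reserved for contract violations: malformed domtblout lines
  (reported with line number), negative windows, identity targets outside
  [0, 1], conflicting genome assignments for one protein, and planting
  requests exceeding genome capacity (reported with the constraint).

# Problem sizes used in validation

The shipped test suite validates against brute-force oracles at the scale
the statistics stabilize while staying quick: 1,000 random hits for the
filter predicate, 200 random hit sets for overlap resolution, a
ten-genome / ~2,000-gene / 25-PUL community for locus recovery, and 50
query–reference pairs at identity targets of 50/70/90% for the novelty
stage, cross-checked pair-by-pair against an independent quadratic-time
dynamic-programming aligner.

# Known limitations

* Model-name→class mapping is prefix-based; a family model with an
  unconventional name falls into OTHER and is ignored by the callers.
* PUL merging is purely positional; regulatory co-transcription evidence
  is out of scope.
* Cohesin–dockerin binding specificity, scaffoldin subtyping and signal
  peptide prediction are not implemented; signal-peptide flags are carried
  as pass-through metadata.
* The novelty stage stores only the best reference per query; all-vs-all
  identity matrices are out of scope.
* Percent identity between very short queries and the significance floor
  interact: queries shorter than ~40 residues cannot reach `min_score` and
  will report no hit.
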