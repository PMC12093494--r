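---
title: "Comparative CAZyme genomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative CAZyme genomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazymeR)
```

## The analysis in one paragraph

Carbohydrate-active enzymes (CAZymes) are classified into six
categories — glycoside hydrolases (GH), glycosyltransferases (GT),
polysaccharide lyases (PL), carbohydrate esterases (CE), auxiliary
redox activities (AA) and carbohydrate-binding modules (CBM) — and,
within each, into numbered families and subfamilies (GH13, GH13_11).
Scanning a proteome with `hmmscan` against a dbCAN-style HMM database
yields one candidate domain match per profile alignment; after removing
weak and mutually redundant matches, the surviving domains, ordered
along each protein, form its *domain architecture*. Counting proteins
per organism — by category, by family, and by the polysaccharide
substrates those families can attack — produces per-organism profiles
whose central statistic is %CAZyme CDS, the percentage of annotated
coding sequences carrying at least one retained CAZyme domain.
Comparative statistics (group medians, Welch tests, regressions on
genome size, PCA of category counts) then quantify differences between
taxonomic and habitat groups.

## Reading domain tables

HMMER3's `--domtblout` is whitespace-delimited with one line per domain
match and 23+ fields. The package's canonical layout puts the protein
in the target column and the CAZyme HMM in the query column, with the
profile length in `qlen`; this is the layout `write_domtblout()` emits
and the round-trip contract the tests enforce. Raw `hmmscan` output
has the two sequences the other way around (the HMM is the *target*,
with its length in `tlen`), so genuine hmmscan files are read with
`protein_is = "query"`. In either orientation the quantity that matters
downstream is the HMM profile coverage

$$\mathrm{coverage} = \frac{\mathrm{hmm\_to} - \mathrm{hmm\_from} + 1}
                           {\mathrm{hmm\_length}},$$

computed on the profile's own coordinates — a short protein fragment
aligned to a small corner of a long profile is a weak annotation no
matter how good its e-value. Coordinates stay 1-based inclusive
end-to-end, the HMMER convention. The parser either parses a line or
fails loudly with its line number; out-of-range coordinates are
rejected, never clamped.

## Filtering: quality, then redundancy

Thresholds (all in `filter_config()`, all configurable):

| parameter          | default | meaning                                        |
|--------------------|---------|------------------------------------------------|
| `min_coverage`     | 0.35    | minimum fraction of the HMM profile aligned    |
| `max_ievalue`      | 1e-15   | independent e-value ceiling, alignments ≥ 80 aa|
| `relaxed_ievalue`  | 1e-3    | ceiling for alignments < 80 aa                 |
| `short_cutoff`     | 80 aa   | boundary between the two ceilings              |
| `overlap_fraction` | 0.5     | tolerated overlap, fraction of shorter interval|

These are the long-standing dbCAN parser conventions; since no single
threshold set is canonical across parser versions, the defaults are
ordinary arguments rather than constants, and the independent e-value
(not the full-sequence e-value) is what is thresholded, because a
multi-domain protein's full-sequence e-value conflates its domains.

Redundancy resolution is greedy: per protein, visit hits by increasing
independent e-value (ties: higher coverage, then canonical family
string, then position — the full key makes the outcome independent of
input order); accept a hit iff its alignment interval overlaps every
previously accepted hit by at most `overlap_fraction` of the shorter of
the two intervals. Greedy best-first is not optimal weighted interval
scheduling, but it is what "retain the high-quality match" means
operationally, and its exact behaviour is pinned by brute-force subset
enumeration in the tests. Overlap is measured on alignment (`ali`)
coordinates, not the wider envelope, because the alignment is what the
architecture displays. By default resolution arbitrates across
families (a GH13 and a CBM48 claiming the same residues cannot both
stand); `same_family_only = TRUE` restricts arbitration to same-family
copies. Same-family hits that survive at disjoint positions are kept
as separate copies — tandem repeats are real biology, not redundancy.

## Architectures and combinatorial patterns

Retained domains are ordered by `ali_from` (ties: `ali_to`, then label)
into strings like `GH23+CBM50+CBM50`, and each protein is classified:

* `alone` — exactly one domain;
* `multi_copy` — ≥ 2 domains, all one family;
* `with_accessory` — ≥ 2 distinct families.

These three classes partition the proteins containing any given family,
an invariant the tests assert. Subfamily labels stay verbatim in
architecture strings; the `granularity` flag decides whether GH13_10
and GH13_11 count as the same family for classification and
co-occurrence (default: they do not, so subfamily-specific
associations such as GH13_11 with CBM48 remain visible). Only CAZyme
domains are visible to this pipeline: a protein whose extra domains are
all non-CAZyme Pfam models will look like `alone`, which is a known
divergence from architecture counts computed over a full domain
database.

## The substrate map

`default_substrate_map()` links families to the eight tracked
substrates (cellulose, xylan, lignin, starch, chitin, dextran, fructan,
pectin) through named enzyme activities and EC numbers, curated from
the CAZyme literature: 17 cellulose-active GH families of which six
(GH6, GH9, GH12, GH44, GH45, GH74) are cellulose-exclusive, the
bifunctional GH13 (starch + dextran, since amylopectin and dextran
share α-1,6 linkages) and GH48 (cellulose + chitin), the GH32/fructan
and CE8/GH28/PL1 pectinase assignments, and so on. EC numbers are
opaque lookup keys — no EC-hierarchy logic. Subfamilies inherit the
parent family's substrates unless a map row names them explicitly.
The shipped map covers the families with explicit literature support;
`load_substrate_map()` reads a 4-column TSV to replace or extend it
(see `inst/extdata/substrate_map_extended.tsv` for a loadable superset
with additional acetyl-xylan-esterase CE families), so a fuller
curation is a data file, not a code change.

## Profiles

%CAZyme CDS divides the number of proteins with ≥ 1 retained domain by
the *annotation-derived* total CDS count — metadata, not the domtblout
universe, supplies the denominator, since proteins without CAZyme hits
never appear in the domain table. The GFF3 path counts distinct CDS
`ID` attributes, so a CDS split across lines counts once. Category and
substrate counts are protein-level set membership (a GH + CBM protein
increments both categories; a GH13 protein increments both starch and
dextran). Family-count matrices are emitted at both protein level and
domain-instance level because downstream mean-abundance displays can
legitimately want either. Habitat (soil/marine/other) is a metadata
column, never inferred from taxonomy.

## Comparative statistics

* Medians are the midpoint of the two central order statistics;
  quartiles use type-7 linear interpolation; spread is the sample SD
  (n−1). These are the defaults of the standard R toolchain, which is
  what comparable analyses report.
* Welch's t-test uses the direct formula with Welch–Satterthwaite
  degrees of freedom, so degenerate zero-variance groups return
  (t = 0, p = 1) or (|t| = ∞, p → 0) instead of erroring; on regular
  input it agrees with `stats::t.test` to machine precision (asserted
  in tests). Pairwise p-values are reported raw by default, with
  `p.adjust` methods available — multiple-testing correction is a
  reporting choice, not a default.
* Regression is `stats::lm` with R² = 1 − SSres/SStot (equal to the
  squared Pearson correlation for one predictor). A constant response
  gives R² = 0 by convention; a constant predictor is an error.
* PCA is `stats::prcomp` on the organisms × 6 category-count matrix:
  centered, unscaled covariance PCA by default (`scale = TRUE` gives
  correlation PCA; it rejects zero-variance columns by name). Each
  component's sign is fixed so its largest-magnitude loading is
  positive, making scores reproducible. Variance fractions are
  λᵢ/Σλ, checked against an independent SVD in the tests.
* The %CAZyme group comparisons default to the percentage column;
  raw counts are present in the same profile table for anyone who
  prefers testing them.

## The synthetic-data generator

`generate_dataset()` stands in for the real download-and-scan workflow
and defines the study conditions under which the package is validated:

* **Taxonomy**: 61 organisms in 3 suborders / 9 families, sampled
  ~70/10/20% (Cystobacterineae/Nannocystineae/Sorangiineae), the
  Nannocystineae marine and everyone else soil.
* **Genomes**: family-specific 2–16 Mb size ranges (two small-genome
  families; the rest 9–14 Mb); total CDS ≈ genome size / 1.1 kb with
  4% multiplicative noise, which makes CDS count regress on genome
  size with R² near 0.97.
* **%CAZyme targets**: per-family normal draws, means 2.2–4.4%
  (highest in Archangiaceae, lowest in the marine families), SD
  0.25–0.45 — the 2–5% band observed in real soil-bacterial genomes.
* **Architectures** are drawn from a weighted template pool seeded
  from the commonly observed patterns (standalone GT2/GT4/CE1/GH23,
  GH23 with one or two CBM50s, GH13_11+CBM48, GH6+CBM4, triplicated
  CE8, GH32 with duplicated CBM66, ...), placed at non-overlapping
  positions with coverage 0.75–0.98 and i-e-values 1e-60…1e-25.
* **Decoys**: overlap decoys copy a true hit shifted by 5–45% of its
  length with a 100–10000× worse e-value — they pass the quality
  filter and must lose overlap resolution to the sharper original;
  noise hits draw coverage below 0.35 and must die in the quality
  filter. With both rates at zero the pipeline must reproduce the
  planted truth *exactly*; with decoys on it must still do so
  (precision = recall = 1), which the tests assert.
* HMM profile lengths are a deterministic hash of the family label
  (100–450 columns), and all randomness flows from one seed, so equal
  seeds give byte-identical files.

`generate_count_matrix()` serves the statistics layer directly: counts
are negative-binomial draws *parameterised by their median* (the NB
mean is solved numerically so the configured median — defaults GH 84,
GT 77, CE 63, CBM 62, AA 19, PL 14 — is the distribution's central
value; dispersions echo realistic overdispersion, and dispersion 0
degenerates to the exact configured value). Categories are drawn
independently, which real data are not: correlated category counts
would concentrate more variance on PC1 than the independent draws do.
That, and the absence of non-CAZyme domains, cross-family HMM
redundancy, draft-assembly fragmentation and annotation errors, bound
what passing tests prove about real data: they validate the machinery
exactly, and the realism of the magnitudes approximately.

## Problem sizes and numerical choices

The test suite runs organisms at 100–300 CDSs (seconds per scenario)
plus one 60-organism recovery scenario; the acceptance script runs the
full 61-organism configuration at realistic CDS counts (~24k planted
proteins, about a minute). Coverage equality is validated to 1e-9 to
absorb decimal round-trips; overlap arithmetic is integer-exact; the
overlap cap is inclusive (exactly 50% of the shorter interval is
tolerated); ties anywhere in sorting are broken by full deterministic
keys. Family labels normalise leading zeros (GH013 → GH13) and strip
`.hmm` suffixes; unknown category prefixes are rejected by name.

## Known limitations

Non-CAZyme domains are invisible, so "alone" means "no other *CAZyme*
domain". The shipped substrate map is the literature-derived core, not
an exhaustive curation — the TSV loader is the extension point. The
greedy resolver can differ from an optimal interval scheduler on
pathological overlap chains. No phylogenetic correction is applied to
group comparisons; groups are treated as exchangeable samples, which
taxonomically structured organisms are not.
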