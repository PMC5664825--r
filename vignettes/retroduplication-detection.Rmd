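---
title: "Detecting and dating LTR-retrotransposon-mediated retrogenes"
author: "retroscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating LTR-retrotransposon-mediated retrogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscan)
```

## The biological problem

Plant disease-resistance genes of the NLR family expand by several
duplication routes. One of them is retroduplication: an mRNA of a
multi-exon parent gene is reverse-transcribed and re-integrated by the
machinery of an LTR retrotransposon. A gene born this way carries a
characteristic syndrome:

* **intron loss** — the copy has fewer exons than its parent, often one;
* a **3' poly(A) tract** downstream of the coding sequence;
* **flanking direct repeats** — the element's paired LTRs and the short
  target-site duplication created at integration;
* residence **inside an LTR element**, either a full-length one (paired
  LTRs still recognizable by an LTRharvest-class annotator) or the
  deletion-degraded remnants of one (LTR-order fragments in a
  RepeatMasker-style table).

Because the two LTRs of an element are identical at integration and then
diverge neutrally, their distance `K` dates the insertion
(`age = K / 2r`, intergenic rate `r = 1.3e-8` substitutions/site/year).
The synonymous distance `Ks` between a retrocopy and its parent dates the
duplication itself (`age = Ks / 2r`, synonymous rate
`r = 6.96e-9` per synonymous site per year). retroscan implements the
whole chain — detection, verification, curation, dating — on standard
annotation inputs, and ships a synthetic-genome generator with a planted
truth table so that every rule can be exercised and scored without
multi-gigabase assemblies.

## The decision procedure

Candidates are collected in two passes. The *full-length pass* takes every
gene whose whole span lies inside a predicted element (nested elements
resolve to the smallest container). The *partial pass* recovers genes whose
element decayed: the union of LTR-order repeat fragments must cover the
gene completely and extend beyond it on both flanks. A gene found by both
passes keeps the full-length label.

Candidates then survive four filters:

1. **TE conflict.** If the gene is covered above a threshold (default 0.5
   of its span) by DNA-transposon or Helitron (RC) annotations, the element
   prediction is distrusted and the candidate is rejected. LINE/SINE
   overlaps never trigger this rule.
2. **Parental verification.** The candidate CDS is locally aligned
   (match +2, mismatch −3, gap open 5, gap extend 2) against the spliced
   CDS of every non-candidate family member (family labels, when present,
   restrict the pool). A parent must cover more than 95% of the query,
   have at least two exons, and have more exons than the candidate — the
   intron-loss criterion.
3. **Multi-gene elements.** When several parent-verified genes share one
   element, exactly one is the retrogene: with equal exon counts, the gene
   with the longest exonic extent; with differing counts, the gene whose
   single longest exon is more than 1.5-fold larger than every exon of its
   neighbours; otherwise the gene with the fewest exons. Ties break by
   longer CDS, then smaller start, so the selection is order-invariant.
4. **Orphans.** Multi-exon candidates with no parent are unclear cases and
   are rejected. Single-exon parentless candidates are kept only when they
   carry a retro signature (poly(A) or direct repeats); they are labelled
   `candidate_signature_only` rather than `retro`, because a `retro`
   verdict always implies a verified parent. This gating of single-exon
   orphans is a design choice of this package: unconditional retention
   would admit arbitrary single-exon annotations inside elements, and
   unconditional rejection would discard copies whose parent was lost.

Finally the gene family is partitioned: finalized retro calls; *ambiguous*
genes (non-retro but covered > 80% by LTR-order repeats — possible
unresolved retro context); and *normal* genes, the comparison class. The
three sets are disjoint and exhaustive by construction, and the pipeline
report's stage counts always reconcile (in = out + rejected at every
filter).

## Signature scanning

The poly(A) detector looks downstream of the CDS end (in transcription
orientation) within a 200-nt window for a run of at least 10 adenines with
at most one interior mismatch; the run's first and last base must match, so
a 9-base run never qualifies via a flanking neighbour. The direct-repeat
detector compares the two flanks of the insertion (the element span for
full-length calls, the gene span otherwise) for a pair of near-identical
(≥ 90%) substrings of 4–20 nt at mirrored offsets; the offset slack is
kept small (5 nt) because a target-site duplication sits immediately at
the insertion boundaries, and allowing arbitrary offsets would make
spurious 4-mer matches likely in random sequence. Homopolymer matches are
not accepted as direct repeats.

## Dating

LTR pairs are aligned globally with free end gaps; gap and ambiguity
columns are excluded; the Kimura two-parameter distance
`K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` is converted to years as
`K/2r`. Saturated pairs (non-positive log arguments) yield "age not
estimable" rather than a number. The model choice (K2P) is this package's
own: it is the standard two-parameter correction for the
transition-biased divergence of neutral repeats, and small numeric
differences against likelihood-based baseml estimates are expected.

Retrocopy–parent pairs are compared with Nei–Gojobori (1986) counting:
fractional synonymous sites per codon (changes to stop codons count as
nonsynonymous), pathway-averaged differences (pathways through stops
excluded), Jukes–Cantor correction per class. `Ka/Ks` is undefined at
`Ks = 0`. Duplication events within a family are grouped by single-linkage
clustering of Ks values (connected components under a Ks cutoff, computed
through `hclust`); the cutoff is a required configuration value
(default 0.1 ≈ 7 MY at the synonymous rate) — no single value suits every
family, and it should be chosen against the family's Ks distribution.
Each cluster is dated by its smallest Ks.

## The synthetic genome

`simulate_genome()` plants, on uniform-random background sequence:

* multi-exon parents (2–8 exons, 50–150 codons per exon, GT..AG introns),
  carrying family labels;
* retro events: the parent's spliced CDS (optionally mutated at 1% per
  site by default, emulating post-duplication divergence), a 15-nt
  poly(A), insertion between a freshly drawn LTR pair (1 kb), a 5-nt
  target-site duplication, and — for the autonomous fraction — a 3-kb
  internal ORF. Each LTR then evolves independently for `age` years at the
  intergenic rate, so the expected pair distance is `2rt`. A configurable
  fraction of elements is degraded: dropped from the element records and
  replaced by overlapping LTR-order fragments, exercising the partial
  pass. A quarter of retrocopies insert in reverse orientation.
* decoys: an element whose gene is 80% covered by a DNA/hAT annotation
  (TE conflict); a parentless 3-exon gene inside an element (orphan); twin
  genes in one element for each discrimination branch; and solo LTR
  fragments.

Substitutions are sampled from the exact K2P transition matrix at the
requested branch length, so distance estimators are unbiased in the
calibration tests. Defaults (2 × 300 kb chromosomes, 24 parents, 20
events at 0.5/1/1.5 MY) were chosen once as a desk-scale genome dense
enough to exercise every rule; the age-calibration analyses use 20
elements with 5-kb LTRs, where the binomial noise of a single LTR pair is
small enough for a meaningful regression.

What the generator deliberately does **not** model: indels and alignment
uncertainty, GC skew and composition heterogeneity, nested element
insertions, gene conversion between LTRs (which rejuvenates real
elements), and realistic repeat landscapes. Passing the recovery tests
therefore shows the decision rules are implemented correctly, not that
detection would be complete on a real, repeat-rich genome.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (the GFF and Bioconductor
  convention); parsers convert nothing, removing a whole class of
  off-by-one errors.
* "Fully contained" means whole gene span inside the element span, strand
  ignored (a retrocopy may insert in either orientation).
* The TE-conflict fraction is measured against the union of DNA/RC
  repeats, so several abutting fragments accumulate.
* Zero-length intervals are constructor errors; saturated distances are
  structured conditions (`retroscan_saturation`), not numbers.
* Representative transcript = longest total CDS, ties to the smallest
  start.
* All iteration orders are sorted by identifiers, and reports contain no
  timestamps: identical inputs give byte-identical outputs.

## What the tests show

The unit and acceptance suites verify: the interval algebra; format round
trips; each curation branch on constructed fixtures (order-permuted); NG86
against an independent brute-force pathway-enumeration oracle; K2P against
its closed form and against `ape::dist.dna(model = "K80")`; single-linkage
clustering against a union-find oracle; exact recovery
(precision = recall = 1) of all planted events on a noise-free genome with
every decoy rejected for its designated reason; recall ≥ 0.9 under
divergence; and an estimated-versus-planted insertion-age regression slope
within [0.85, 1.15]. Problem sizes (600-kb genomes, ~23 events) keep the
whole suite in a couple of minutes while still covering every branch.
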