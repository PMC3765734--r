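---
title: "DGE-tag profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DGE-tag profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgetag)
```

# The measurement model

A DGE-tag library reduces each transcript to one short sequence tag.
NlaIII cuts cDNA at every CATG; the bead-bound 3′ fragment is retained, so
the informative site is the 3′-most CATG of the transcript. MmeI then cuts
17 bp downstream of the ligated adaptor junction, releasing a
CATG-anchored 21-mer whose variable 17 nt identify the transcript. Deep
sequencing of these tags turns transcript abundance into tag copy number:
an "open" quantification that needs no probe design and no genome, which
is why the protocol suits non-model organisms.

`dgetag` implements the computational half of this design:

1. `extract_virtual_tags()` / `build_tag_index()` — in-silico digestion of
   a transcript FASTA into the reference tag database.
2. `extract_read_tags()` / `filter_tags()` — raw tag counting and the
   three cleaning rules (N-containing tags, adaptor-derived tags, copy
   number below 2).
3. `map_tag()` / `map_library()` — tag-to-gene assignment permitting at
   most one mismatch.
4. `normalize_counts()`, `ac_test()`, `call_de()`, `classify_pattern()` —
   quantification, replicate-free differential expression, and the
   two-way similar/different (S/D) classification of cross-species
   developmental profiles.
5. `venn_partition()`, `coexpression_fraction()`,
   `summarize_libraries()` — set-overlap analysis and per-library summary
   tables.
6. `sim_config()`, `simulate_reference()`, `simulate_libraries()` — a
   generator with recorded ground truth, so 1–5 are testable end to end.

`run_pipeline()` drives 1–5 (or a fully simulated study) from one
configuration object, writing each stage's output as TSV and a manifest
of checksums; the exported functions are the package's interface, and the
driver exists so a whole run is reproducible from a single call.

# Canonical tags and the reference index

The canonical tag is defined as the 3′-most CATG with at least 17 clean
(non-N) nucleotides downstream. This is a chemistry argument, not a
convention: the oligo-dT bead retains the 3′-terminal restriction
fragment, so only that site yields a sequenced tag. `all_sites` mode is
kept because truncated cDNAs can expose internal sites. Tags are
sense-strand only (the library is oligo-dT primed and strand-specific),
coordinates are 0-based offsets of the anchor's first base, and a
candidate window containing N contributes no tag, mirroring the read-side
N filter. The anchor is a parameter (`anchor = "GATC"` gives DpnII-style
anchoring) but only the NlaIII default is exercised by the test suite.

Two transcripts may legitimately share a canonical tag (shared 3′ ends,
paralogs); the index maps each distinct tag to the full transcript set
and the mapper classifies such hits as ambiguous rather than guessing.

# Cleaning rules and their order

Three rules define clean tags: no character outside A/C/G/T, not derived
from a configured adaptor, and copy number at least `min_copy` (default
2 — singletons are presumed sequencing-error artifacts at typical error
rates and depths). The rule *order* (N → adaptor → copy number) affects
only the per-rule removal counts in the `FilterReport`, never the
surviving set; it is fixed so reports are reproducible. The adaptor rule
drops a tag equal to a configured adaptor sequence or to its tag-length
prefix; adaptor sequences are kit-specific and therefore configuration,
with the Illumina small-RNA/DGE 3′ adaptor prefix as the documented
default.

One caveat is inherited from the protocol's own bookkeeping: singleton
fractions are only meaningful *before* the copy-number filter (clean
libraries contain no singletons by construction), so `singleton_stats()`
reports on the raw distribution and the two numbers should not be mixed.

# Mapping with one mismatch

Assignment is two-tier: an exact hit always beats any one-mismatch hit;
within a tier, one candidate transcript means an assignment and two or
more mean `ambiguous`. The one-mismatch candidate set is found by hashed
lookup of all 51 Hamming-1 neighbors (17 positions × 3 substitutions),
which the test suite proves equivalent to a brute-force Hamming scan on
random instances. There is no score blending: a 1-mismatch hit to a
highly expressed gene never competes with an exact hit to another gene.

Ambiguous tags are counted as *mapped* in the library-level mapping
statistics (they did hit the reference — this matches how mapping ratios
are conventionally reported) but are excluded from per-transcript counts
by default; `ambiguous = "drop"` removes them from both and
`"distribute"` splits their counts equally among candidates. Which policy
the original studies used is typically unstated; the default keeps
quantification conservative while leaving the summary statistic
comparable.

# Quantification and the exact test

TPM is the default unit: `tpm = 1e6 * count / depth`, with depth the
library's clean-tag total (not the mapped total — unmapped clean tags
still consumed sequencing capacity). RPKM is provided because the
surrounding literature reports it, but dividing a *single-tag-per-
transcript* count by transcript length has no statistical justification;
it is documented as a compatibility output only.

With one library per condition there are no replicates, so dispersion
modeling (negative binomial, as in edgeR/DESeq2) is unavailable. The
field-standard choice for SAGE-type data is the exact tag-count test of
the Audic–Claverie family, and it is declared as this package's design
decision, with all thresholds explicit and configurable. The
implementation conditions on the pooled count: under the null of equal
relative abundance, `y | (x + y = t)` is `Binomial(t, N2/(N1+N2))`, and
the two-sided p-value doubles the smaller tail (capped at 1). Two
formulations circulate — this conditional form, and the predictive form
that fixes `x` and sums the tail over `y′ ≥ y`. Their upper tails are
identical term for term (a negative-binomial/binomial duality), but only
the conditional form is exactly symmetric under swapping the libraries,
which is the property a two-sample test should have; that decided the
choice. Arguments are canonicalized before summation so symmetry holds to
the last bit, and tails are accumulated in log space so depths in the
millions and counts in the hundreds of thousands (the largest published
tag counts exceed 200,000) neither underflow nor overflow.

Direction calls require both `fdr <= alpha` (Benjamini–Hochberg across
the genes detected in the pair; default 0.05) and
`|log2 fold change| >= lfc_min` (default 1) on TPM with pseudocount 1.
The fold-change gate matters in deep libraries: at depths of 10^5–10^7, a
biologically trivial 10% difference on a highly expressed gene is
"significant" by p-value alone. The pseudocount is applied to TPM rather
than raw counts because depths differ between libraries.

At `x = y` and equal depths the test returns exactly 1, and under a
simulated null its rejection rate at `alpha = 0.05` stays below nominal
(the discrete conditional test is conservative) — both are asserted in
the test suite.

# The S/D pattern rule

Published cross-species tables classify each gene's developmental
profile as "similar" (S) or "different" (D) without printing a rule. The
rule formalized here: compare the two species within each stage with the
exact test and the fold-change gate; the gene is D if and only if at
least one stage yields a significant direction call. `classify_pattern()`
applies this to a single gene (no multiplicity to correct; `alpha`
applies to the raw p-value), and `classify_patterns()` applies it across
a matrix with BH correction per stage. On the 20 published exemplar
profiles shipped in `helicoverpa_pattern_profiles()`, this rule
reproduces the authors' label for every row — the acceptance script
reports the agreement fraction rather than asserting it, since the
authors' own thresholds are unknown and other datasets need not agree.

# Summary tables and rounding

`summarize_libraries()` assembles per-stage counts, species totals (each
total is defined as the sum of its four stage values) and mapping
ratios, `100 * mapped_unique_tags / unique_clean_tags`, rounded
*half-up* to two decimals. Half-up rather than banker's rounding is
deliberate: ratio cells in published tables of this kind are half-up
rounded, and reproducibility of printed cells requires matching the
convention (e.g. 68.3751% must print as 68.38, which `round()`'s
round-half-even can violate one step earlier in the pipeline at exactly
representable halves). The mapping *gene* ratio divides by the size of
the reference actually mapped against; it is reported only when that
size is supplied, because it is a property of the user's reference, not
of the library.

# The synthetic-data generator

The generator emulates a two-species, four-stage (embryo, larva, pupa,
adult) tag study:

* **Reference**: `n_transcripts` random sequences (default 500) of
  200–400 nt at GC 0.42 (a typical insect transcriptome value). A CATG
  site with a full 17 nt window is inserted into any sequence lacking
  one, so essentially every transcript is taggable; untaggable
  references for error-path testing are constructed by hand.
* **Expression**: per-transcript baseline weights are log-normal
  (`meanlog = 0`, `sdlog = 1.2`), with per-transcript multiplicative
  stage effects (`sdlog = 0.5`) shared between the species.
* **Differential expression**: a `de_fraction` (default 10%) of
  transcripts receive an exact between-species fold change of
  `de_log2fc` (default 2) — injected as weight *swaps* within matched
  transcript pairs (weights `b` and `b * 2^lfc`, stage effects shared
  within the pair). Pairing is what makes the ground truth clean: library
  composition is preserved exactly, so every non-DE transcript is an
  exact between-species null and every DE transcript changes by exactly
  the nominal fold change. A one-sided multiplicative injection would
  instead shift *all* genes' relative abundances (strongly so under
  heavy-tailed weights), making "null" genes systematically non-null
  under any within-library normalization — a generator artifact, not a
  pipeline property.
* **Reads**: each library draws `depth_per_library` tag reads (default
  10^5): a fixed `adaptor_read_fraction` (default 1%) of contaminants
  (anchor + adaptor prefix, so they traverse extraction and are caught by
  the adaptor filter), the rest multinomial over transcripts. Each read
  is its transcript's canonical tag with i.i.d. per-base substitution
  (default 0.002) and N-call (default 0.002) errors over the 17 nt
  payload. Reads are materialized as 21 nt (anchor + tag); an optional
  FASTQ writer pads with adaptor sequence to exercise longer-read
  handling.
* **Determinism**: each library uses an RNG stream derived from the
  master seed by a stable hash of (species, stage), so results are
  independent of simulation order and byte-identical across reruns.

## Why `sdlog = 1.2`

Real deep libraries (~6 × 10^6 tags) span about five decades of tag copy
number. The package's validation runs are scaled down ~60× to 10^5 reads
over 500 transcripts so the test suite stays fast. Scaling depth down
while *keeping* the full dynamic range would push roughly a third of
transcripts below the detectability floor — a regime the full-depth
experiment does not have — so the default emulates the real experiment's
per-gene coverage rather than its raw dynamic range. Heavy-tailed
configurations (`expression_sdlog` near 2) reproduce the
singleton-dominated raw libraries typical of SAGE and are exercised
explicitly in the singleton-fraction test. Users simulating at realistic
depths should widen the spread accordingly.

## What passing tests do and do not show

The generator produces i.i.d. per-base errors, uniform across positions
and libraries, no PCR duplication structure, no position-specific
Illumina error profile, no MmeI star activity, and one pooled sample per
library (as the emulated study design had — no replicates). Passing the
recovery and DE checks therefore demonstrates correctness of the
*computations* under the model the pipeline assumes, not robustness to
real-data pathologies such as composition shifts between conditions,
3′-bias interacting with site choice, or error hotspots. The S/D rule in
particular inherits the exact test's behavior: with no replicates,
"different" means "inconsistent with sampling from identical relative
abundance", not "biologically validated".

# Validation scale and numerical choices

The shipped checks run at: 1,000 random transcripts for extraction vs
brute-force scan; 100 random instances (≤ 300 reference tags, ≤ 200
queries) for hashed-vs-brute-force mapping equivalence; a full simulated
study (500 transcripts × 8 libraries × 10^5 reads) for parameter
recovery (Pearson r ≥ 0.99 on log1p counts), DE recall (≥ 0.8) and
empirical FDR (≤ 0.1); 10,000 simulated null pairs for test calibration;
and agreement of `ac_test()` with an independent direct-summation oracle
to 10^-9 relative for pooled counts ≤ 200. Degenerate inputs (empty
libraries, empty references, all-zero genes, single-stage summaries) are
exercised in the unit suite. Ties in the exact test are handled by
including the observed outcome in both tails before doubling, the
conservative convention.
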