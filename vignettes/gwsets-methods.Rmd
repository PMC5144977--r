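---
title: "Methods: gene measures, U-scores and hypergeometric set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene measures, U-scores and hypergeometric set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwsets)
```

# The problem

A genome-wide association study (GWAS) produces one p-value per SNP; a
genome-wide expression study (GWES) produces one per gene. Neither speaks
directly about biology's working unit of coordination, the pathway. Moving
from SNPs to pathways requires three layered annotations — positions,
SNP-to-gene assignment, gene-to-pathway membership — and two statistical
steps: collapsing SNP evidence to a per-gene measure, and testing each
pathway for over-representation of high-ranking genes. This vignette
documents exactly how `gwsets` does each step, which knobs exist, and which
choices were genuinely open.

# The knowledge store

`kb_build()` materialises four tables in one SQLite file: `snpmaps`
(rsid, build, chrom, pos), `genemaps` (gene_id, symbol, build, chrom, start,
end, strand), `geneSets` (pid, name, category, url, size) and `geneInfo`
(gene_id, symbol, pid, category). Conventions:

* **Coordinates** are 1-based, fully closed intervals on both ends. This is
  the dbSNP/Entrez convention, and every interval test in the package
  (`snp_to_gene()`, region queries) treats boundary positions as inside.
* **One span per gene and build.** Gene databases list transcripts; this
  store keeps a single record per `(gene_id, build)` using the union span —
  minimum start, maximum end over supplied transcript rows. `start` is
  always the low coordinate regardless of strand (a minus-strand gene still
  has `start < end`; its TSS is at `end`).
* **PIDs** are consecutive integers in GMT input order starting at 1.
  Because the upstream databases do not document a portable numbering, PIDs
  are store-local: results should be matched across stores by set name and
  category, never by PID.
* **GMT member tokens** that are all digits are taken as gene IDs; anything
  else is resolved through an optional symbol map and otherwise dropped with
  a warning and a count in the build report. Both dialects circulate in the
  wild, so the parser accepts a mixture. A duplicated rsid within one build
  aborts the build (it would silently shadow a position); a SNP present in
  only one build is fine — build catalogues genuinely differ in coverage.

# SNP-to-gene assignment

`boundary_spec(up_kb, down_kb)` extends the transcribed span before the
interval test: `up_kb` kilobases beyond the transcription start site and
`down_kb` beyond the termination site, following transcription direction, so
on the minus strand the extensions swap ends. The default 2 kb / 2 kb is the
window conventionally used to capture proximal regulatory variants; with
symmetric boundaries the strand logic cancels, which the test suite checks
by flipping every strand. The window is clamped at position 1; no upper
clamp is applied because chromosome lengths are not stored. A SNP inside
several (extended) spans yields one pair per gene — assignment is
deliberately many-to-many, and the `location_class` column
(`within` / `upstream_flank` / `downstream_flank`) records where in the
window the SNP fell. Whether asymmetric boundaries should be strand-aware is
not settled by any published worked example (only the symmetric default is
exercised there); we chose strand-awareness because "upstream" has a
biological direction, and we document it here because other tools differ.

# Gene effect measures

For the K SNP p-values assigned to one gene, `gene_measure()` offers:

* `minP` = p₍₁₎ — powerful, but its null distribution shifts with K;
* `2ndP` = p₍₂₎ — discounts a lone outlying SNP;
* `simP` = minᵢ{K·p₍ᵢ₎/i} — Simes' combination, a valid p-value under
  positive dependence, adjusted for K;
* `fishP` = P(χ²₂ₖ ≥ −2Σ ln pᵢ) — Fisher's combination; sensitive to
  accumulation of moderate signal.

Numerical decisions: the Fisher statistic uses natural logs (only −2Σ ln p
is χ²-distributed); `simP` is capped at 1 as a guard although the raw
minimum cannot exceed 1; p-values of exactly 0 are **rejected, not
clamped** — a zero would send −2 ln p to infinity silently, so the caller
must decide on a floor (the fixture generator uses 1e-300). For a
single-SNP gene, `2ndP` has no second value: the default falls back to
p₍₁₎ and flags the row (`fallback = TRUE`), keeping the gene universe
identical across methods; `strict = TRUE` drops such genes instead. With one
SNP, `fishP` equals that SNP's p-value analytically — the suite asserts the
identity to ten significant digits.

# U-scores

Measures with different null distributions are not comparable; the U-score

$$U_i = \frac{\sum_j I(M_j < M_i) + 0.5\sum_j I(M_j = M_i)}{L}$$

is the midrank empirical quantile of gene *i* among all L measured genes.
The tie sum includes *j = i* (each observation contributes 0.5 to its own
count), which makes a fully tied pair score (0.5, 0.5) and forces the mean
of any U-score vector to be exactly 0.5 — an identity, not an approximation,
and a property test in the suite. Implementation is
`(rank(ties = "average") − 0.5)/L`, algebraically identical to the formula.

# Enrichment tests

Both tests condition on a category (e.g. KEGG) and share one sampling
model: a universe of L genes, l of them "selected", a set with S members in
the universe, and the overlap K. Then

* effect = K/S − l/L, the excess probability that a set gene is selected;
* SE = √((l/L)(1 − l/L)/S), the binomial standard error of K/S at the null
  rate l/L;
* p_e = P(X ≥ K) for X ~ Hypergeometric(L, S, l).

**Tail convention.** The observed overlap is included in the tail
(P(X ≥ K), not P(X > K)). The reference worked result this package is
validated against (L = 5267, l = 27, S = 25, K = 4 → p = 6.44e-06) is only
reproduced by the ≥ convention; the printed formula in the source's summary
table (1 − Σ₀ᴷ) is a one-off typo for 1 − Σ₀ᴷ⁻¹ and is treated as such.

**Universe definition.** For CGEA (`enrich_test1()`), L counts the distinct
genes annotated to *any* set of the category — not all genes genome-wide.
For USGSA (`enrich_test2()`), L additionally intersects with the measured
genes, and S and K are counted inside that universe. Restricting the
universe to the category keeps the null hypothesis "candidates distribute
like other *annotated* genes", which is the question a pathway test asks.
Selection for USGSA is `U ≤ α` (ties at the threshold included), α = 0.05
by default.

`hypergeom_upper_p()` accumulates the tail from `lchoose()` terms in log
space with a max-shift, so p-values far below double underflow of any single
binomial coefficient remain exact; the suite checks every parameter tuple
with L ≤ 25 against direct enumeration (tolerance 1e-12) and a deep tail
(~1e-270) against the log-scale distribution function.

# Permutation adjustment

Testing hundreds of sets inflates the family-wise error. `perm_adjust()`
uses the min-p (Westfall–Young) scheme: each permutation redraws the l
selected genes uniformly without replacement from the universe — for USGSA
this is exactly a permutation of U-scores across genes — recomputes every
set's p_e, and records the minimum. A set's adjusted p is the fraction of
permutation minima at or below its observed p_e, reported two ways: the raw
proportion (which can be exactly 0 and matches how such adjusted p-values
are conventionally printed) and the add-one corrected (x+1)/(B+1), which is
a valid p-value and the safer default for inference. Redrawing the selection
rather than permuting each set's own overlap is what makes a p of 0
attainable at finite B; a pointwise permutation of an exact test could never
beat its own p_e.

`build_null_table()` runs the same stream once (default B = 10000) and
stores, per permutation, the overall minimum p_e and the minimum within each
set-size stratum; `get_enrich2_p()` then returns the empirical exceedance
fraction as a step function — no interpolation. Because both functions share
one generator, the same seed gives bitwise-identical streams, and the
table-based adjusted p equals `perm_adjust()`'s raw proportion exactly (a
tested invariant). The table format (an R list serialised with `saveRDS()`,
carrying a universe fingerprint of category, α, L, l, gene IDs and set
sizes) is this package's own; a table is refused for any universe whose
fingerprint differs. Per-size strata are provided because a min-p over all
sets is conservative for an individual set; the stratum column conditions on
set size, the only parameter p_e depends on besides K.

`uscore_proportion_test()` covers the complementary question for a *fixed*
candidate list: do more than the expected α₀ of its genes carry U ≤ α₀?
Each gene contributes a binary indicator; the test is a one-sample,
one-sided t-test of the indicator mean against α₀ with sample SD and
n − 1 degrees of freedom. A vector of identical indicators has zero variance
and is rejected with a diagnostic rather than returning an infinite t.

# The synthetic fixture generator

`generate_fixture()` emulates every input the pipeline consumes: per-build
SNP and gene maps, GMT files, GWAS and GWES result tables, and a
`truth.json` recording what was planted. Defaults are 1000 genes packed
without overlap on 2 chromosomes (spans 5–50 kb, gaps 2–20 kb, capacity
30 Mb with a hard error on infeasible packing), 4000 SNPs placed uniformly,
and 200 sets of 30 genes sampled with overlap allowed from the gene pool —
one of which (PID 1) is planted at strength δ = 0.1. Planted genes' p-values
(and the p-values of SNPs within 2 kb of a planted gene span) are drawn from
Beta(δ, 1), a family that stays in (0,1), is stochastically below uniform
for δ < 1, and reduces to the uniform null at δ = 1; any one-knob
sub-uniform family would serve. GRCh38 coordinates are the GRCh37 ones under
a per-chromosome shift, with the last 2% of SNPs left GRCh37-only to mimic
build-coverage gaps. All output is written with explicit formatting so a
fixed seed reproduces byte-identical files.

What the generator does **not** emulate: linkage disequilibrium (SNP
p-values are independent given the planted set), allele frequencies,
genotypes, gene-density/size biases, and correlated pathway membership
beyond random overlap. Passing the recovery tests therefore demonstrates
that the machinery is correct and calibrated under independence, not that
any particular real-data finding would replicate; on real GWAS data,
LD-induced correlation among SNPs in a gene makes `fishP` anti-conservative
in particular.

# Validation problem sizes

The suite validates recovery and error control at the generator's default
conditions (200 sets, planted size 30, δ = 0.1, α = 0.05): the planted set
must rank first by exact p-value in at least 18 of 20 seeds, and on pure
null fixtures the smallest add-one-corrected min-p adjusted p-value (B = 200
permutations) must exceed 0.05 in at least 17 of 20 seeds — the binomial
slack around a true 5% FWER. Exhaustive hypergeometric enumeration runs over
all universes up to L = 25; shared-fixture tests use a smaller store (300
genes, 2000 SNPs, 2 × 50 sets of 10) to keep the full suite under a minute
apart from the replicated-seed blocks.

# Known limitations

* No liftover: each build's coordinates must be supplied; the store only
  holds both side by side.
* No LD-aware or permutation-based *gene* tests; measures treat SNP
  p-values as exchangeable evidence.
* The enrichment universe never extends beyond annotated genes; genes
  outside every set of the category are invisible to the test.
* `2ndP`'s single-SNP fallback makes it coincide with `minP` for such genes;
  a study dominated by single-SNP genes should prefer `strict = TRUE` or a
  different measure.
* The permutation adjustment controls FWER, not FDR; with thousands of sets
  a min-p criterion is stringent by design.
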