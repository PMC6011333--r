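---
title: "funcmark: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{funcmark: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcmark)
```

`funcmark` builds and exploits a functional-gene qPCR marker for the
bacterial ACC deaminase group (*acdS*). This vignette explains the models
behind each stage, the defaults and their units, the numerical choices,
and what the synthetic-data generators do and do not demonstrate.

## Reference curation by catalytic residues

ACC deaminase and D-cysteine desulfhydrase are close homologs; sequence
databases for one are contaminated with the other. The discriminating
signal is a small set of catalytic residues, expressed as ungapped 1-based
positions on a reference protein (defaults: Lys51, Ser78, Tyr295, Glu296,
Leu322 on a *P. kilonensis* F113-style anchor). `map_reference_columns()`
maps each position through the alignment by counting non-gap reference
characters; `filter_by_key_residues()` keeps a sequence only if it carries
exactly the expected amino acid at every mapped column.

Two deliberate choices:

* **A gap at a required column is a discard**, with status `incomplete`
  rather than `mismatch`. A deleted catalytic residue cannot support
  activity, but partial-length database entries that simply do not cover
  the position are a different situation from an observed substitution, so
  the two are distinguishable downstream rather than silently merged.
* **Dereplication** (`dereplicate()`) collapses entries only when both the
  nucleotide sequence is 100% identical *and* the species label matches;
  the lexicographically smallest id is retained so the result is
  reproducible regardless of input order.

CDS inputs are assumed in-frame (frame 0); `translate_cds(best_orf =
TRUE)` switches to three-frame selection by fewest internal stops for
inputs of unknown frame. Codons containing ambiguity symbols translate to
`X`, stops to `*`.

## Oligonucleotide thermodynamics

`melt_temp()` implements the two-state nearest-neighbor model with the
unified stacking parameter set and terminal initiation terms. Entropy is
salt-corrected as `ΔS + 0.368 (N−1) ln[Na+]` with `N−1` stacking steps,
and

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/x)} - 273.15$$

with `x = 4` for non-self-complementary oligos (`x = 1` plus a −1.4
cal/mol/K symmetry term for self-complementary ones). Defaults are 1 µM
primer (the assay's reaction concentration) and 50 mM monovalent salt;
both are explicit `oligo()` fields. The model predicts that Tm rises with
strand concentration and GC content, properties the test suite checks.

Hairpin and dimer screens are **complementarity-run heuristics**, not
free-energy folding: a hairpin needs two antiparallel complementary runs
of ≥ 4 bases (`min_stem`) separated by ≥ 3 unpaired bases (`min_loop`); a
dimer needs a complementary run of ≥ 8 bases anywhere or ≥ 4 bases
anchored at either 3' terminus (extension-competent). Run-based rules are
deterministic and can be verified against exhaustive scans, which the test
battery does; the trade-off is that they ignore stability differences
between AT- and GC-rich stems.

## Primer screening

Conserved-window enumeration makes explicit what is often done by eye:
every alignment window of 25–30 columns whose columns all have majority
fraction ≥ 0.80 and gap fraction ≤ 0.10 yields a majority-consensus
forward candidate and its reverse complement (ties in the majority base
break A < C < G < T). Candidates are non-degenerate; the downstream
mismatch tolerance (≤ 3 per primer) plays the role degenerate bases would.

`evaluate_pair()` scores the six assay criteria — Tm window 60–67 °C,
clean structure, |ΔTm| ≤ 1 °C, product ≤ 300 bp, full database coverage at
≤ 3 mismatches, and no non-target amplicon — and reports the measured
value for each, so a failure is attributable. The verdict is the
conjunction, and relaxing any threshold can only turn failures into
passes (monotonicity, property-tested).

In-silico PCR (`insilico_pcr()`) additionally requires an **exact
3'-terminal trinucleotide match** for a primer to count as bound, on top
of the overall mismatch cap: polymerase extension requires a matched 3'
end. The rule is configurable (`three_prime_exact = 0` disables it).
Coordinates are 0-based half-open on the plus strand and the amplicon
includes both primer footprints, matching the usual product-size
convention (a 25 + 83 + 25 construct reports a 133-nt product).
`design_pairs()` walks candidate regions with a `stride` (default 10
columns) so that the evaluated pairs sample distinct regions instead of
near-identical shifted windows, and pre-filters on per-oligo criteria
before the expensive database scans.

## qPCR standard curves and copy numbers

`fit_standard_curve()` regresses the **mean Ct of the replicates** at each
dilution on log10 concentration (the convention for instrument standard
curves); `per_replicate = TRUE` fits all points instead for sensitivity
analysis. The reported error of the method is the residual mean square
about the fitted line with divisor n − 2. Efficiency is
`E = 10^(−1/slope) − 1`; the −1 form is used throughout because only it
maps the conventional acceptable slope span (−3.9 to −3.0 cycles/decade)
onto 80–115% efficiency, with −1/log10(2) ≈ −3.32 corresponding to perfect
doubling. Copy numbers follow `mass · N_A / (bp · 660)` with
N_A = 6.02214076 × 10²³ and 660 g/mol per base pair.

Samples whose Ct exceeds the Ct of the most dilute standard are flagged
`below_limit` and still reported — "not quantifiable" is information, not
a zero.

## Amplicon community profiling

Reads are kept when 120–160 nt long with no ambiguous call (the assay's
amplicon is ~133 nt). `denoise()` is a deliberately simple surrogate for
vendor denoising: exact dereplication with per-sample counts, plus
optional removal of dataset-wide singletons — the singleton-free dataset
is the one used for rarefaction and diversity. Chimera removal is a
pass-through hook; commercial pipelines' proprietary steps are not
imitated.

OTUs are built by greedy centroid clustering at a 3% divergence radius:
uniques are processed in decreasing abundance (ties by id), and a sequence
joins the first centroid with identity ≥ 0.97, else founds a new OTU.
Identity comes from an end-gap-free global alignment (match +1, mismatch
0, gap −1; terminal gaps free) computed in C++, with identity = matches /
aligned columns (terminal overhangs excluded). The traceback prefers
diagonal over up over left so results are deterministic; an independent
plain-R dynamic program in the test suite reproduces every decision.
Global alignment is appropriate because amplicons are near-equal length;
the same machinery drives best-hit classification (`classify()`), which
assigns the best hit's genus with ties broken by smallest id — single
best hit, not lowest common ancestor, mirroring single-best-hit BLAST
usage against a curated core database.

Alpha diversity reports Shannon entropy in nats, **Simpson as dominance
λ = Σp²** (higher = less diverse; `simpson_form = "gini"` gives 1 − λ) —
the dominance form is the one under which Shannon and Simpson move in
opposite directions across samples — and Chao1 as
`S_obs + n₁²/(2n₂)`, with the bias-corrected `S_obs + n₁(n₁−1)/(2(n₂+1))`
when no doubletons exist. Subsampling is hypergeometric (without
replacement, via `vegan::rrarefy`) and seeded; rarefaction curves are
means over repeated subsamples and are checked against the closed-form
expected richness. Bray–Curtis comes from `vegan::vegdist`.

## Distances and correlation with host phylogeny

`k2p_distance()` implements the Kimura two-parameter correction
`K = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with P and Q the transition and
transversion fractions over sites where both sequences have an unambiguous
base; saturated pairs (non-positive log arguments) raise an explicit error
rather than returning NaN. Plant distances may equally be supplied
precomputed as a square TSV.

`distance_correlation()` vectorizes the matched upper triangles and
reports Spearman's rho. Two p-values are available: the plain asymptotic
(and, for small tie-free inputs, exact) Spearman p, which treats the
pairwise distances as independent — they are not, since m genotypes yield
m(m−1)/2 correlated pairs — and a Mantel-style permutation p
(`method = "mantel_spearman"`, `p = (count+1)/(perms+1)`, label
permutations of one matrix, seeded). The plain Spearman is the default
because it is the convention this assay family uses; the Mantel option is
the statistically defensible check, and the vignette's advice is to report
both.

## Synthetic data: what it shows and what it does not

`gen_family()` emulates the ortholog/paralog structure the curation stage
must resolve: targets conserve every policy residue and two conserved
primer-landing windows (by default positioned so a ~133-nt product exists),
with 2% background per-base substitution; paralogs diverge at 30%
(roughly 70% identity, the ballpark of a diverged paralogous family) and
carry forced amino-acid violations at the policy positions. Substitutions
in targets avoid the policy codons entirely, so truth labels stay exact.
`gen_reads()` draws reads multinomially with independent per-base
substitution errors and optional 3' trimming; `gen_standards()`/`gen_ct()`
produce Ct data from a known line (default slope −1/log10(2), i.e. 100%
efficiency, over the 5 × 10⁻⁹ to 5 × 10⁻¹⁵ g/µL dilution series in
triplicate) with Gaussian Ct noise.

These generators make every stage testable against known truth, but they
are idealizations: no quality-score structure, no indels or chimeras, no
length-dependent error, no PCR amplification bias, and paralog divergence
is i.i.d. rather than phylogenetically structured. Passing tests therefore
demonstrate algorithmic correctness (each operation equals its brute-force
oracle, round trips recover truth) — not that the assay performs
identically on real soil amplicon data.

## Problem sizes and determinism

The test suite uses deliberately small instances — oligos ≤ 30 nt,
templates ≤ 500 nt, families of ~40 sequences, read sets of a few
hundred — because each operation is compared against an exhaustive oracle
whose cost grows steeply; these sizes exercise every code path while
keeping oracle equivalence checks exact. All stochastic steps take
explicit seeds and use a single seeded stream per call; every generator is
bit-reproducible under a fixed seed.

## Known limitations

* Tm values are model values; no attempt is made to match any particular
  desktop tool's output, and divalent-cation corrections are out of scope.
* Alignments and phylogenetic trees are consumed, not produced (use
  MUSCLE/MAFFT and your tree builder of choice upstream).
* The denoiser is a simplified stand-in, so OTU counts on real data are
  not comparable to vendor-pipeline counts.
* `coverage()` scans both orientations of each database entry
  independently of the partner primer; a primer pair whose two footprints
  overlap is rejected by geometry, not flagged specially.
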