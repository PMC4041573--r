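---
title: "Methods: scoring positional effects from pooled FR/FL mutant libraries"
author: "dmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring positional effects from pooled FR/FL mutant libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscan)
```

## The experimental design being modelled

`dmscan` analyses a deep mutational scan of an FMN-binding fluorescent
protein (FbFP), a 137-residue LOV-domain reporter carrying the engineered
C62A substitution. The screen works by iterated error-prone PCR: in each of
ten cycles the gene is mutagenised, transformed, and colonies are classified
by eye as fluorescent (function retained, FR) or non-fluorescent (function
lost, FL). Two hundred variants per class per cycle are picked; FR variants
become the PCR templates of the next cycle, so non-deleterious mutations
accumulate while every FL variant is one mutagenesis step away from a viable
template. Plasmid DNA from all cycles is pooled at equal mass per cycle, and
each pool is sequenced as 50-bp single-end reads.

The analytical idea is simple: a residue where mutations keep landing in the
FL pool but never in the FR pool is required for function. The package
quantifies this as the **positional effect**

$$ e_i \;=\; \frac{n^{FL}_i}{n^{FL}_i + n^{FR}_i}, $$

where $n^{L}_i$ is the number of read-level amino-acid substitution
occurrences at residue $i$ in library $L$ after background filtering.
$e_i = 1$ marks a fully intolerant (sensitive) residue, $e_i = 0$ a fully
tolerant one, and a residue with no observed mutations has an *undefined*
effect — it is reported as missing, never imputed, because both extremes
are meaningful.

## Pipeline stages and their assumptions

### Reference model

The plasmid is a circular sequence with two annotated ORFs: the scored
target gene and an ampicillin-resistance control gene. Coordinates are
0-based half-open on the plasmid; residues are 1-based per ORF, so reports
match conventional residue labels (C62, L65). Minus-strand ORFs are
reverse-complemented before translation; all scoring happens in protein
space. The package ships a *synthetic* stand-in plasmid
(`write_synthetic_reference()`) that reproduces the construct's layout — a
137-codon target with alanine at 62 and leucine at 65, a 286-codon
control ORF on the opposite strand — but not the true vector sequence,
which no packaged result depends on. The annotated ORF is treated as
exactly the scored region; vector linker codons are not part of it.

### Read mapping

Reads are placed by exhaustive ungapped scoring at every offset of both
strands of the circular plasmid (a doubled sequence scans the
origin-spanning junction). This is deliberate: at plasmid scale an exact
scan is affordable and sidesteps seed-sensitivity corner cases, and it is
what the brute-force oracle in the test suite checks placement-for-placement.
Acceptance follows CLC-style parameters: a placement must reach the
similarity fraction (default 0.8, i.e. at most 10 mismatches in a 50-bp
read); the mismatch cost defaults to 2 (the more permissive of the two
commonly used values, configurable to 3); insertion and deletion costs are
3. A local-alignment rescue pass runs only when no ungapped placement
qualifies; reads rescued with indels are flagged and excluded from protein
calling, because a 50-bp read with an indel cannot be frame-trimmed
reliably. Reads with several equally good placements are dropped — only
uniquely mapped reads are analysed. The length fraction (default 0.5) only
constrains gap-rescued, clipped placements; it is an assumption, not a
reported setting, and is exposed as a parameter.

### Translational trimming and substitution calling

A mapped read is trimmed to the maximal full-codon span inside each ORF:
`(3 - phase) mod 3` bases are removed at the biological 5' end and the
remaining overhang modulo 3 at the 3' end, so between zero and two bases
disappear at either end. The span is translated with the standard genetic
code and compared to the wild-type protein. Synonymous changes produce no
call; stop gains are called as `*`; codons containing `N` are uncallable
and skipped. Codons covered by only one or two bases contribute neither
calls nor coverage — partial codons cannot be translated, so counting them
as coverage would deflate frequencies.

Counting is at read level ("occurrence counts"): a substitution supported
by 30 reads counts 30, with no deduplication and no phasing of co-occurring
mutations. This matches the scale of the published per-residue counts,
where single enriched substitutions reach counts near 200 while the
per-substitution average is an order of magnitude lower.

### Sequencing-error background

Because every plated variant must keep its ampicillin-resistance gene
intact, amino-acid substitutions called in the control ORF can only be
sequencing errors. The per-library error rate is

$$ r \;=\; 100 \times \frac{\text{control-ORF substitution occurrences}}
{\text{reads contributing to the control ORF}} \quad [\%], $$

and any target-gene substitution whose frequency falls strictly below $r$
is discarded. For the frequency denominator the package defaults to the
per-position codon coverage of the substitution's residue, with the
ORF-wide read count available as an alternative (`denominator = "reads"`).
The coverage denominator is the default because it compares each call
against the number of reads that could actually have produced it, and
because the published per-residue count tables contain filtered entries
(e.g. a surviving count of 7 against roughly 3,700-fold coverage) that are
only consistent with a per-coverage comparison. The filter operates per
distinct `(position, amino acid)` entry; whether to filter per position or
per substitution is ambiguous in prose descriptions of such pipelines, and
the per-substitution choice is the conservative one (it never lets a rare
artefact ride on a common neighbour).

### Scoring and cutoff calibration

After filtering, the FR/FL substitution identities are partitioned into
shared and library-unique sets, the positional effect is computed per
residue, and a sensitivity threshold is calibrated against a standard set
of known functional sites (for this protein, the 15 FMN-binding residues
identified structurally). The calibration rule is not dictated by the
experiment, so the package uses a transparent, reproducible one: sweep all
observed effect values as candidate thresholds and maximise Youden's
J = sensitivity + specificity − 1 against the standard set, breaking ties
toward the higher (stricter) threshold. Residues with undefined effect are
negative calls. The rule is pluggable — any function of the profile can
replace it — and the report records the threshold, the sensitive set, and
how many standard sites it captures.

No multiple-testing correction is applied: the positional effect is a
descriptive enrichment ratio, not a hypothesis test. Per-position binomial
confidence intervals can be derived from the reported counts if needed.

### Dimer-interface hydrophobicity

For the nine β-sheet residues that mediate LOV-domain homo-dimerisation,
substitutions are classified by the hydrophobicity of the *substituted*
amino acid. The partition is a standard side-chain classification —
hydrophobic = {A, V, L, I, M, F, W, C}, proline counted hydrophilic —
with glycine excluded entirely (it is aliphatic and fits neither class);
stop gains are likewise excluded. The classification is configurable, since
no single partition is canonical.

## The synthetic generative model

The simulator exists so the whole pipeline can be tested against known
ground truth; it emulates the screen's design, not every artefact of real
sequencing.

* **Mutation spectrum.** Error-prone PCR substitutions follow a
  strand-complement-symmetric spectrum parameterised by the
  transversion/transition ratio (default 0.9 — a slight excess of
  transitions, matching what the mutagenesis kit reports) and the A/T
  versus G/C template balance (default 1.0 — no compositional bias).
* **Mutations per PCR.** Uniform on 1–6 substitutions per cycle, the range
  the mutagenesis protocol specifies. Uniform is the least-informative
  choice consistent with the stated range and is configurable.
* **Fitness map.** 30 of the 137 residues are designated deleterious; every
  non-wild-type amino acid at such a site, any stop gain, and loss of the
  terminal stop codon are lost-class. The phenotype of a variant is the AND
  over its sites (epistasis-free). This mirrors the analytical assumption
  that every FL variant is explained by at least one deleterious site — the
  simulator must share that assumption for parameter recovery to be a fair
  test of the scoring, not of the assumption.
* **Selection cycles.** Candidates are generated and routed by phenotype
  until each class holds 200 variants per cycle; FR variants seed the next
  cycle's templates. Ten cycles give the study-scale libraries of 2,000
  variants each.
* **Sequencing.** Reads are uniform 50-bp fragments of the whole variant
  plasmid (so most reads cover the backbone and control gene, as in the
  real pool), cycles are weighted equally, and substitution errors are
  applied per base at rate 3.7×10⁻⁵ with constant Q40 qualities. That rate
  was calibrated by Monte-Carlo so the control-gene protein-level error
  estimate lands at ≈0.13%, the value the real libraries show; roughly,
  each contributing read spans ~46 in-frame bases of which ~70% of random
  base errors change the amino acid, giving ≈35 amino-acid errors per read
  per unit base-error rate.

What the simulator deliberately omits: PCR amplification bias, duplicate
reads, quality-score degradation along the read, indel sequencing errors
(an indel mode exists only to exercise the frameshift filter), and any
epistasis. Passing the recovery test therefore shows that the pipeline
correctly inverts its own generative assumptions at realistic depth and
noise — it does not certify behaviour on real data with those artefacts.

## Numerical and design choices

* **Problem sizes.** The packaged end-to-end test runs the full study
  design (10 × 200 variants per class) with 30,000 reads per library on a
  ~1.5-kb synthetic plasmid, which yields roughly 1,000-fold codon coverage
  of the target — about a quarter of the study's depth, chosen so a
  complete run stays comfortably inside a desktop test budget while keeping
  every count well above the filter's resolution. All sizes are plain
  configuration entries.
* **Determinism.** Every stochastic stage draws from R's global RNG; the
  pipeline seeds it once from the config, and identical seed + config give
  byte-identical reports (no timestamps in outputs; the JSON carries the
  config hash instead).
* **Ties and degenerate inputs.** Mapping ties break toward the leftmost
  reference coordinate, then the plus strand, and multi-locus ties are
  dropped as non-unique. Zero-coverage positions have undefined effect.
  Row normalisation of heatmap matrices leaves all-zero rows at zero. The
  error-rate estimator refuses a zero-read control ORF rather than
  returning 0%.
* **Known limitations.** The mapper is exact but O(plasmid × read) per
  read, fine for plasmids, wrong tool for genomes. Multi-mutation phasing
  is out of scope, so the effect score attributes FL passenger mutations
  at tolerant sites to those sites; with deep libraries this inflates FL
  counts roughly equally across tolerant residues and is absorbed by the
  calibrated threshold, but it is a real ceiling on per-substitution
  interpretation. One published per-residue effect value (residue 65)
  disagrees in the third decimal with the ratio of its own published
  counts (0.875 printed vs 55/62 = 0.887 computed); the package computes
  the formula and documents the discrepancy rather than reproducing the
  printed rounding.

## A worked example

```{r example, eval = FALSE}
library(dmscan)

cfg <- default_config(seed = 1, n_reads = 10000)
cfg$simulate$n_cycles <- 4
cfg$simulate$n_per_class <- 100
report <- run_pipeline(cfg, "dms_run")

report$error_rates$fr$rate_percent   # control-gene error, %
report$partition                     # shared / unique substitution sets
report$threshold                     # calibrated effect cutoff
report$recovery                      # sensitivity/specificity vs ground truth
```

The run directory contains the simulated FASTQ files, the ground-truth
variant table, filtered tally TSVs, the positional-effect table with the
sensitive-residue flags, heatmap matrices, and `report.json` — the single
numeric source of truth for the run.
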