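---
title: "Methods: allopolyploid subgenome statistics in subgenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allopolyploid subgenome statistics in subgenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgenomics)
```

`subgenomics` implements the statistics a comparative-genomics study of an
allopolyploid needs after assembly and annotation are done: which chromosome
belongs to which subgenome, how long ago the progenitors diverged, which
subgenome lost more genes, where dosage changed through tandem duplication
or a supernumerary (B) chromosome, what the ploidy of an individual is, and
how much deleterious load its genes carry. Every estimator can be exercised
against a synthetic allotetraploid with recorded ground truth, so the whole
stack is testable without any external sequencing data.

## The synthetic allopolyploid generator

`simulate_allopolyploid()` builds an ancestral gene complement (random sense
codons, no internal stops) and duplicates it into subgenomes A and D. Its
defaults are the study conditions the downstream estimators assume.

**Divergence model.** Substitution proposals arrive as a Poisson process at
rate `subgenome_divergence_ks / 2` per nucleotide site per subgenome (both
lineages diverge from the ancestor). Each proposal draws one of the three
alternative bases uniformly; synonymous proposals are always accepted,
nonsynonymous ones with probability `omega` (dN/dS, default 0.3), and
proposals creating a stop codon are rejected so the CDS stays translatable
for the effect annotator. Because every synonymous opportunity is accepted,
the expected number of accepted synonymous substitutions per NG86 synonymous
site equals the configured Ks — the generator is calibrated in the same
currency the estimator measures. At two-fold degenerate sites the
synonymous process is a two-state chain rather than a four-state
Jukes–Cantor chain, so saturation behaviour differs slightly from the JC
ideal; at the divergences of interest (Ks up to ~0.5) the induced bias on
the recovered Ks mode is well below the KDE bandwidth, which the test suite
verifies at Ks 0.1, 0.2 and 0.5. Configurations with Ks ≥ 3 are rejected:
expected synonymous differences approach the 3/4 saturation point where the
JC correction is undefined.

**Fractionation, tandems, repeats.** Each ancestral gene is deleted from
subgenome A with probability `loss_fraction_A` (default 0.15) and from D
with `loss_fraction_D` (default 0.10) — biased loss with D dominant, in the
direction the retention statistics should detect. Retained genes receive
Poisson(`tandem_rate`) adjacent tandem copies (same family id, slight extra
divergence). Each subgenome carries a private 500-bp repeat consensus
planted `repeats_per_chromosome` times per own chromosome and
`round(own / repeat_family_fold)` times per partner chromosome. The copy
counts are deterministic and only the positions are random: this pins the
planted between-homoeolog fold exactly at `repeat_family_fold`, so phasing
recovery can be tested right at the filter boundary. Intergenic spacers
descend from shared ancestral sequence and diverge at the synonymous rate,
which matters for B-fragment tracing (a fragment's true source must beat its
homoeologous copy).

**B chromosome.** `simulate_b_chromosome()` concatenates fixed 300-bp
segments: an exact count `round(b_source_fraction * n_segments)` copied from
recorded, repeat-mask-free main-chromosome coordinates (with per-base noise
`b_segment_noise`), the rest random filler. The exact count makes the
recorded truth fraction equal the configured one, so recovery error is
attributable to the tracer alone.

**Observations.** `simulate_observations()` places heterozygous sites along
every CDS: position *i* with NG86 synonymous opportunity *f~i~* becomes a
synonymous heterozygote with probability `heterozygosity_syn * f_i` and a
nonsynonymous one with probability `heterozygosity_nonsyn * (1 - f_i)`, so
each class's expected heterozygosity per NG86 site equals the configured
rate — the quantity `pi_by_class()` should recover. Each site carries one
divergent copy out of the homoeologue-resolved copies (the configuration
that produces the observed read-fraction peaks), giving a true alternate
fraction of 1/2 at ploidy 4 and 1/3 at ploidy 6; total depth is
Poisson(`mean_depth`) and alternate depth Binomial. The windowed depth track
scales with local copy number (main chromosomes at the 2-copy baseline, the
B at `b_copies`) plus a `mismap_depth_fraction` floor on the B. What the
generator does **not** emulate: mapping error beyond that scalar, indels,
recombination, GC or mappability bias, and read-level artifacts — so green
tests certify the statistics under their stated models, not robustness to
real-library pathologies.

All draws come from R's generator seeded from `config$seed` (B chromosome
uses `seed + 1`, observations `seed + 2`), so identical configurations give
byte-identical FASTA/GFF3/BED/TSV outputs.

## Subgenome phasing

Allopolyploid subgenomes carry private repeat families expanded after
hybridisation. `count_kmers()` counts canonical k-mers (lexicographic
minimum of forward and reverse complement; k odd, default 13) per
chromosome. `select_differential_kmers()` keeps k-mers with genome-wide
count ≥ `min_total` (default 100) and a between-homoeolog fold change
(max/min of raw counts) ≥ `min_fold` (default 2) in a majority of pairs. A
pseudocount guards only the zero denominator (fold = max + 1 when the minor
count is 0): an unconditional `(max+1)/(min+1)` pseudocount would push a
planted fold of exactly 2 below the threshold and discard the very signal
the filter is meant to keep. Homoeologous pairing is an explicit input (from
synteny or simulation truth) rather than inferred — separating concerns that
published phasing tools bundle. `assign_subgenomes()` clusters chromosomes
on length-normalised differential profiles with correlation distance and
average-linkage hierarchical clustering cut at two groups, checks that every
pair splits, and reports a silhouette-style separation score. Labels are
arbitrary up to a global swap; evaluation uses
`assignment_matches_truth()`, which treats the swap as identity. An absent
signal (no k-mer passes, or a pair does not split) is a loud error, never a
silent empty assignment.

## Syntelogs, Ks and dating

`find_syntelogs()` chains shared-family matches into collinear blocks
(longest strictly increasing chain by dynamic programming, both
orientations, minimum `min_block` matches) and pairs genes one-to-one.
`compute_ks()` implements Nei–Gojobori (1986): fractional site counting
(changes to stop codons count toward nonsynonymous sites so S + N = 3 ×
codons), observed differences averaged over every minimal mutational pathway
between codon pairs (pathways through stop codons excluded unless none
avoids one), and Jukes–Cantor correction per class, flagged undefined at
p ≥ 3/4. The estimator is validated to 1e-9 against an independent
exhaustive-enumeration oracle. `ks_modes()` evaluates a Gaussian KDE
(bandwidth 0.02 Ks units, grid step 0.005) on [0, 5] — values above the
Ks = 5 saturation filter are excluded globally — and reports local maxima
above 10% of the global maximum. `calibrate()` turns a dated Ks peak into a
rate r = Ks / (2T) (both lineages accumulate substitutions), and
`date_divergence()` is linear in Ks. The pipeline's default anchor (Ks 0.453
at 70 My) is the value implied by dating a Ks-0.2 peak at 30.9 My; the
package asserts the internal consistency r = 0.2/(2 × 30.9 My) ≈ 3.24e-9
rather than treating the unprinted calibration mode as data.

## Fractionation bias

`build_retention()` flags each ancestral gene by survival in A and D and
asserts the partition identity (both + A-only + D-only + neither = total) on
every run. `loss_bias_test()` is a df-1 goodness-of-fit chi-square of the
differentially lost counts against 50:50, with a closed-form statistic
`(a − d)² / (a + d)`; because the published test construction for this
quantity is ambiguous, a 2×2 contingency variant (subgenome × retained/lost,
Pearson without continuity correction) is reported alongside whenever the
both-retained count is supplied. `retention_windows()` profiles retention in
sliding windows along the ancestral order (window 100 genes and step 10 at
field scale; the pipeline's desk-scale default is 20/5), keeping a shorter
terminal window so every gene is covered; with non-overlapping windows the
occupancy-weighted mean reproduces the global retention fraction to 1e-12.

## Tandem duplication and set statistics

`find_tandem_arrays()` reports maximal same-family runs with at most
`max_gap` intervening genes (default 10, the MCScanX-style convention, since
no published criterion exists); array members count as tandem duplicates,
and detection is idempotent. `go_enrichment()` is the one-sided Fisher exact
(upper hypergeometric tail) per term over a flat term→gene map — ontology
propagation is upstream's job — with Bonferroni, Šidák, Holm and
Benjamini–Hochberg adjustments over the tested terms (those with ≥ 1
population hit). `set_overlap_test()` reports |overlap|/|set1| and the
one-sided Fisher p of the 2×2 membership table; `lineage_specific_terms()`
partitions term sets into Venn classes.

## B-chromosome copy number and origins

`window_coverage()` aggregates a depth table into 1-kb windows, flags
windows ≥ 50% under a repeat mask, and flags as artifacts windows exceeding
3× the genome-wide median in this *and every other supplied lineage* —
operationalising the observation that collapsed organellar DNA and assembly
errors spike everywhere while genuine dosage differences do not.
`b_copy_ratio()` is the ratio of unmasked mean depths (B versus all other
chromosomes); with main chromosomes at a 2-copy baseline the ratio
approximates B copies / 2, and ratios ≤ 0.4 are interpreted as absence with
residual mismapping. Masked windows can never influence the estimate, and
the ratio is exactly linear in B depth. `trace_origins()` tiles the B into
300-bp fragments (terminal remainder kept when ≥ 150 bp), seeds each into
the main chromosomes by exact 15-mer matches on both strands, scores
ungapped alignments at each seeded placement, and calls a fragment
"primary" when its best placement is unique and reaches ≥ 80% identity over
≥ 50% coverage — thresholds chosen as documented conventions since the
published analysis names no mapper settings. The sourced fraction is
n_primary / n_fragments.

## Ploidy from the MAF distribution

`filter_sites()` applies the published depth filters: total depth 20–200
and minor-allele depth > 7, read strictly as ≥ 8 and applied to the minor
allele (the stricter of the two possible readings; both are exposed as
flags). `maf_profile()` folds each site to min(ref, alt)/total, estimates a
Gaussian KDE (bandwidth 0.02) with reflection at the 0.5 boundary — without
reflection the tetraploid mode, which piles up at 0.5, is shrunk inward —
and calls the primary mode: [0.40, 0.50] tetraploid-like (an allotetraploid
with homoeologue-resolved mapping is functionally diploid), [0.30, 0.35]
hexaploid-like, anything else ambiguous. The unfolded alternate fraction is
reported alongside, but the call uses the folded MAF so reference polarity
cannot bend the density.

## Effect classes and deleterious load

`annotate_effects()` re-implements CDS-level consequence annotation: each
variant is placed in codon context (strand-aware), the alternate codon is
translated, and the change is classified synonymous (LOW), missense
(MODERATE) or nonsense (HIGH); HIGH or MODERATE counts as deleterious,
mirroring the convention of the standard annotators. Frameshifts and splice
effects are not modelled because the simulator emits SNVs only. The
annotator is checked against a codon-table oracle on all 576 single-base
codon mutations. `pi_by_class()` computes single-individual diversity — the
study design has one genome per lineage — as the per-site expected
heterozygosity 2p(1−p)·n/(n−1) with n = 2 allele draws and p estimated from
read depths, summed per class and divided by the NG86 fractional site totals
of the annotated CDS. NG86 denominators (rather than raw CDS length) keep
πN/πS comparable across genomes with different codon usage; whether the
published denominators were all sites or covered sites is unstated, and this
choice is the documented one. `ratio_table()` formats per-accession
summaries at the conventional printed precision (six decimals, ratio to
two).

## Pipeline, problem sizes and reproducibility

`run_pipeline()` executes simulate → phase → syntelogs/Ks → fractionation →
duplication → B chromosome → ploidy → diversity and collates one report;
any stage failure aborts with the stage name, and the report carries the
seed and a config hash so reruns are verifiable (`identical()` across runs
is part of the test suite). The bundled configurations are desk-scale by
design: the default demo uses 3 chromosome pairs × 40 genes; Ks-mode
recovery uses 1,000 pairs of 300 codons; ploidy recovery uses ~180 kb of
CDS with heterozygosity 0.03 so that ≥ 5,000 sites survive the depth
filters (the MAF mode depends on allele fraction and depth, not on het
density, so the elevated rate changes power, not location); π recovery uses
the generative rates 0.003/0.0015 over ~2 Mb of CDS. Known limitations:
NG86 with JC correction (no ML codon models), greedy block chaining rather
than full synteny search, ungapped fragment alignment, SNV-only simulation,
and a scalar mismapping model.
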