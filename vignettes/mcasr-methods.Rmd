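---
title: "Methods: identifying mitotic chromosome-associated small RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying mitotic chromosome-associated small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcasr)
```

## The analysis model

`mcasr` identifies small RNAs that remain bound to isolated mitotic
chromosomes across washes of increasing stringency. The unit of analysis is
the *read cluster*: a group of aligned reads whose 5′ ends lie within a
chaining threshold of each other, standing in for one small-RNA species.
Working at the 5′ end rather than over full alignments reflects how small
RNAs are produced — Drosha/Dicer and PIWI processing yields sharply defined
5′ termini, while 3′ ends are ragged.

The pipeline assumes:

* reads arrive already aligned (any aligner; uniquely mapped reads are the
  analysis substrate, matching Bowtie `-m 1` style alignment),
* a species' association strength is proportional to its read count within a
  library, so between-library comparability is achieved by RPM alone (no
  TMM/DESeq-style scaling — with one library per condition and a shared
  protocol, composition-robust normalisation has nothing to estimate), and
* genuine chromosome association expresses itself as *stability*: similar
  RPM across washes, rather than a high value in any single one.

## Stage-by-stage choices

**Read filters.** Reads longer than 30 nt are removed (`max_read_length`,
nt): the library preparation size-selects inserts below ~30 nt, so longer
alignments are gel-purification background. The filter applies to the
aligned length. Only uniquely mapped reads are kept; uniqueness comes from
the `NH` tag when present, with `MAPQ >= 20` as the configurable fallback
for inputs lacking it. For the removal accounting, a read that is both long
and multi-mapped counts as removed-for-length, mirroring the order of the
upstream processing (trimming and length selection precede alignment
bookkeeping). BED input carries no mapping metadata and is treated as
uniquely mapped.

**Clustering (`cluster_gap = 15` nt, strict `<`).** The pairwise rule
"5′ ends less than 15 nt apart belong together" is applied as its transitive
closure — single-linkage chaining over sorted 5′ ends — because that is the
unique partition consistent with the pairwise rule. 15 nt is the minimal
length of annotated mouse miRNAs, so two distinct miRNA species cannot fall
in one cluster. The boundary is strict: a 14-nt gap merges, a 15-nt gap
splits. Strands are clustered separately; small-RNA species are inherently
stranded, and merging antisense reads would fuse, for example, a sense miRNA
with an antisense TSSa RNA. The gap threshold is a parameter, so the
sensitivity of the catalogue to it can be examined directly.

**Representative position and cluster span.** A cluster is positioned at its
highest-frequency 5′ end (the mode). Ties are broken toward the 5′-most
position in transcript orientation (smallest coordinate on `+`, largest on
`-`) — a deterministic, documented choice; the mode is usually unique in
real data. Cluster length is the distance between the 5% and 95% quantiles
of the 5′-end multiset, computed as nearest-rank order statistics
(`ceiling(p * n)`-th value) so coordinates stay integral; a single-read
cluster has length 0. Libraries dominated by genuine small RNAs show almost
no clusters longer than 30 nt, which is the diagnostic this statistic
exists for.

**RPM and the cut-off (`cutoff_fraction = 0.90`).** RPM is
`read_count / total_mapped × 1e6`, with the denominator equal to the reads
that survived all filters and entered clustering — the reads actually used
downstream. (An externally supplied denominator is accepted for
compatibility with pipelines that normalise against all mapped reads.)
"Highly associated" clusters are the shortest RPM-ranked prefix whose read
sum strictly exceeds 90% of the condition's reads; the RPM of the last
cluster in the prefix is the cut-off, and boundary ties are included so the
selected set is well defined. Because the prefix is minimal, removing its
lowest-RPM tie group always drops coverage to at most the target fraction —
a property the tests verify by brute force over prefixes.

**Cross-condition matching (`match_tol = 15` nt).** How clusters were
matched between libraries is an open design point: the package pools every
condition's representative positions and re-clusters them with the same
single-linkage `< 15` nt rule. This reuses a tested operator and is
symmetric and transitive by construction, so the result cannot depend on
the order conditions are supplied in. The anchor position of a matched
cluster is its deepest member's representative position (ties: smallest
coordinate).

**Stability (`stability_lo = 0.5`, `stability_hi = 2`, open interval).**
For each wash pair (X, Y), R = RPM_X / RPM_Y must satisfy 0.5 < R < 2,
strictly: a cluster exactly two-fold different fails. Ratios involving a
zero RPM fail the pair — no pseudocount is added, because "stably
associated" presupposes presence in both conditions and a pseudocount would
let a cluster absent from one library pass on noise. Passing all three wash
pairs is algebraically equivalent to max(RPM)/min(RPM) < 2 over the three
washes; the tests assert this identity on random triples. The pair sets are
additionally restricted to clusters above the cut-off in both members of
the pair (a strict mode requiring all three conditions is available via
`require_all_conditions`). The interphase control (NC) is matched and
reported but never filtered on: the criterion defines mitotic association,
and the NC contrast is descriptive.

**Classification.** Final clusters are tested in the order miRNA → piRNA →
TSSa → unannotated; the sequence encodes annotation confidence (miRBase
coordinates are the most precisely curated) and the first hit wins. "Falls
into" is anchor-point containment — the representative 5′ position inside
the annotation interval on the matching strand — which is robust to ragged
cluster edges; full-span containment would make membership depend on a
single stray read. TSSa windows are −100..+200 nt of the TSS on the sense
strand and −400..0 nt on the antisense strand, offsets in transcript
orientation, the TSS base itself included in both; windows are clipped at
the chromosome start with a warning. Among multiple hits within one
category the interval with the nearest midpoint is reported.

**Statistics.** RPM distributions between conditions are compared by
two-sided Wilcoxon rank-sum; the implementation uses the exact null
distribution for small tie-free samples and the tie-corrected normal
approximation otherwise. The miRNA-versus-rest read-count comparison uses
Welch's t-test — the safer default when only "t-test" is specified, since
equal variances cannot be assumed between annotation classes. The top-n
Venn overlap is assessed by a Monte-Carlo permutation test (k random sets
of the observed sizes drawn from the matched-cluster universe,
add-one-corrected p-value) — a documented stand-in, since no named test is
canonical for k-way overlaps. PCA is computed on the log10(RPM + 1)
cluster-by-condition matrix with per-cluster centering; log transformation
prevents the handful of dominant clusters from absorbing all variance, and
raw-RPM PCA remains available. No multiple-testing correction is applied;
the report's p-values are nominal, isolated pairwise tests.

## What the simulator emulates — and what it does not

`generate_truth()` / `simulate_reads()` reproduce the *statistical*
structure of the experiment on a 2.4-Mb three-chromosome genome:

* **Retention archetypes.** 8 `stable_high` loci with near-equal weight in
  BA/LS/HS (ratios ≤ 1.11) and 20-fold lower weight in NC; 6 `hs_labile`
  loci stripped 25-fold by high salt; 6 `nc_specific` interphase loci; 1580
  `low_background` loci; plus 2% uniform-noise reads per library.
* **Abundance skew.** The 8 stable loci — 0.5% of the 1600-locus roster —
  carry 93–96% of each wash library's expected reads, emulating the
  real-data regime where well under 1% of clusters account for the vast
  majority of reads and the 90% cut-off is reached within a handful of
  clusters.
* **5′-end dispersion.** Read 5′ ends scatter around a locus's canonical
  end by a rounded Gaussian (sd 1 nt, truncated at ±7 nt by rejection).
  Real within-cluster dispersion is uncharacterised beyond being small;
  the truncation bound keeps any planted cluster within the 15-nt chaining
  radius, so jitter can never split a planted locus.
* **Geometry.** Loci sit on a 600-bp grid with ±50 bp scatter, giving ≥500
  nt separation on either strand — planted clusters cannot merge, and no
  locus can fall inside another locus's annotation (the widest window,
  antisense TSSa, reaches 450 nt from an anchor). Annotation files are
  emitted consistently with each locus's truth class; `novel` loci overlap
  nothing.

Reads are simulated directly as alignments: sequence content, quality
scores, adapter contamination, ligation bias and multi-mapping are *not*
modelled (a flag-only non-unique generator exists purely to exercise the
uniqueness filter). Passing tests on this fixture therefore demonstrates
the correctness of the clustering/cut-off/stability/classification logic
and its end-to-end composition — not robustness to alignment artefacts,
repeat-derived multi-mapping, or annotation-version drift in real
libraries.

Identical configurations (including the seed) give byte-identical output;
per-condition streams derive deterministically from the master seed.

## Problem sizes and numerical checks

The test suite verifies the clustering partition against a brute-force
union-find over all read pairs on 100 random instances up to 5000 reads;
cut-off minimality against prefix enumeration on 100 random tables;
end-to-end recovery on the default fixture (4 × 100,000 reads), where the
final set equals the 8 planted stable loci with sensitivity 1 and FDR 0 at
zero jitter and mean sensitivity ≥ 0.95 across 20 seeds at jitter sd 1 nt;
and type-I error calibration of both tests at α = 0.05 over 1000 null
simulations. These sizes make the full suite run in about a minute while
keeping every Monte-Carlo band far wider than its standard error.

## Known limitations

* The matching rule collapses clusters closer than 15 nt across conditions;
  two distinct species offset by < 15 nt would merge (they would also merge
  within a library).
* RPM-only normalisation means strong compositional shifts between
  conditions (one species exploding in one wash) distort all ratios; the
  stability criterion partially guards against this but cannot remove it.
* Classification trusts the supplied annotation; an unannotated call means
  "absent from these tracks", not "novel" in a biological sense. Novel-miRNA
  prediction (hairpin structure, conservation) is out of scope.
* With one library per condition there is no within-condition replication,
  so no dispersion estimate and no differential testing — the catalogue is
  a filter, not an inference.
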