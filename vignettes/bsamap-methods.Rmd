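---
title: "Mapping a recessive locus by bulked segregant analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus by bulked segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

## The problem

A qualitative trait segregating 3:1 in an F2 population points to a single
fully recessive locus. Bulked segregant analysis (BSA-seq) localizes it
without genotyping individuals: DNA from the two phenotypic extremes — here
a wild-type bulk with intact epicuticular wax and a glossy mutant bulk — is
pooled (30 individuals per bulk) and sequenced to ~30× per pool. At a site
linked to the causal locus the two pools diverge in allele frequency; at
the causal site itself the divergence takes a characteristic shape.

`bsamap` implements the complete desk-scale workflow: simulation of the
experiment, pool-level filtering, per-site statistics, a sliding-window
genome scan, candidate ranking against the recessive "ideal frequency",
and coding-consequence annotation of candidate indels.

## The statistical model

Let $f_{wt}$ and $f_{gt}$ be the mutant-allele read fractions of the two
pools at a biallelic site. The package computes four per-site statistics:

* **Euclidean distance (ED)** over both allele coordinates,
  $\mathrm{ED} = \sqrt{(f_{gt}-f_{wt})^2 + ((1-f_{gt})-(1-f_{wt}))^2}
  = \sqrt{2}\,\lvert f_{gt}-f_{wt}\rvert \in [0, \sqrt 2]$.
  The $\sqrt 2$ factor is the biallelic restriction of the multi-allele
  definition; any monotone variant gives identical ranks.
* **G-statistic**: the likelihood-ratio statistic of the 2×2 pool × allele
  read-count table, $G = 2\sum o \ln(o/e)$ with margin-based expectations
  and $0\ln 0 = 0$.
* **Δ-AF**: the signed difference $f_{gt} - f_{wt}$.
* **Ideal-frequency distance**: at the causal site of a recessive trait
  the mutant bulk is fixed ($f_{gt}=1$) and the phenotypically wild-type
  bulk is a 1/3 : 2/3 mixture of homozygous wild-type and heterozygous
  individuals, so its mutant allele fraction is $1/3$ (a 1:2
  mutant:wild-type allele ratio). The distance to the ideal vector
  $(1, 1/3)$,
  $d_{\mathrm{ideal}} = \sqrt{(f_{gt}-1)^2 + (f_{wt}-\tfrac13)^2}$,
  is small exactly where a recessive causal variant would sit.

ED is averaged in 1 Mb windows advanced by 100 kb (mean, not sum, so
variant density does not masquerade as signal); windows above the
genome-wide 99% quantile are merged into candidate regions; sites inside
them that fall in coding or promoter sequence are ranked ascending by
$d_{\mathrm{ideal}}$ and the smallest 5% (ceiling rounding, so a non-empty
eligible set always yields at least one candidate) are reported.

## What the simulator emulates — and what it does not

`simulate_bsa()` generates the full experiment under one seed with a fixed
stream order (site placement → F2 genotypes → bulk membership → WT-pool
reads → GT-pool reads):

* Two fully inbred, opposite-homozygous parents; every placed site is
  informative. Sites where parents share an allele are not simulated —
  the shared hom-alt filter would remove them anyway.
* F2 gametes follow a Markov walk along each chromosome with Haldane
  recombination fractions $r = \tfrac12(1-e^{-2d/100})$ (no crossover
  interference) at the default 1 cM/Mb; optional suppressed intervals
  scale the local rate to emulate pericentromeric blocks that produce
  very large linked regions.
* Phenotype is strictly recessive (mutant class iff dosage 2 at the
  causal site); bulks of 30 are drawn uniformly at random per phenotype
  class — the package takes the view that membership was not stratified,
  which the experimental description leaves open.
* Pooled reads: depth Poisson(30) per pool per site (a fixed-depth mode
  exists for deterministic tests); alt reads Binomial with a symmetric
  per-read error of 0.001. The causal variant is emitted as a 2-bp "AA"
  insertion, the lesion class the workflow ultimately annotates.
* The F2 population size defaults to 240 — not a published design value;
  it is the smallest round number at which the recessive quarter of the
  population (~60) comfortably exceeds the 30 individuals each bulk
  needs.

Not modeled: read-level artifacts (mapping error, indel realignment),
GC/depth covariation, multi-allelic sites, residual parental
heterozygosity. A green simulation test therefore establishes that the
*statistical* machinery recovers a recessive locus under the stated
sampling model, not that the pipeline is robust to alignment pathology.

## Numerical and design choices

* **Pool "genotypes"** for the shared-het and shared-hom-alt filters are
  reconstructed from allele fractions (hom-ref ≤ 0.1, hom-alt ≥ 0.9,
  no-call below depth 5) because caller genotypes are not part of the
  package's inputs. Thresholds are configurable; sites that cannot be
  called are never removed on missing evidence.
* **Depth filter 25–250** is applied to the *combined* depth of both
  pools by default (it brackets the ~60× expectation of two 30× pools);
  a per-pool mode is available because the convention is ambiguous in
  the field.
* **Window anchoring** is at position 1 with inclusive 1-based bounds
  (window $k$ covers $[k\cdot\mathrm{step}+1,\ k\cdot\mathrm{step}+
  \mathrm{window}]$); BED exports convert to 0-based half-open. Anchoring
  is not standardized anywhere; fixing it makes the brute-force test
  oracle trivial.
* **Region threshold** uses the type-7 empirical quantile (linear
  interpolation), genome-wide by default with a per-chromosome flag.
* **Ideal-frequency distance operates on read fractions**, not on
  discretized genotype-frequency vectors: the read counts are the
  observable, the two formulations agree at the causal pattern, and a
  genotype-vector form would require unidentifiable assumptions about
  pool composition. No switch is shipped for the alternative.
* **Translation** uses the standard nuclear code; protein length counts
  residues strictly before the first stop (so a 419-residue protein
  truncated by a frameshift to 234 residues is reported as 419 → 234).
  A non-ATG start warns rather than errors.
* **Exonic depletion** is tested with an exact binomial comparison of
  the observed exonic variant count against the genomic exonic fraction
  — the one-sample analogue of a Fisher comparison of proportions.

## Known limitations

The headline parameter-recovery experiment (one 20 Mb chromosome, 2000
sites, bulks of 30, 30×) localizes the causal locus only to roughly the
megabase scale, not reliably within a single window. This is a property
of the stated world, not of the implementation: at 1 cM/Mb the chromosome
spans 20 cM, every site is linked to the causal locus, and the 60
chromosomes of a bulk carry only ~12 crossovers in total, so pool allele
frequencies drift in steps of 1/60 at megabase scale — larger than the
expected ED gradient per megabase. An independent Poisson-crossover
re-implementation of the simulator reproduces the same localization
limit. Sharper localization requires genetically longer chromosomes
(higher cM/Mb or physically larger maps) or larger bulks; both raise the
crossover density that the method's resolution is built on. Real designs
with hundreds-of-Mb chromosomes and genome-wide background behave like
the multi-chromosome simulations in the test suite, where unlinked sites
make the candidate region unambiguous.

The consequence annotator handles variants contained in a single CDS
interval; splice-site disruption, UTR effects and transcript decay are
out of scope.
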