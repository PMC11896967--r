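# bsamap

Bulked segregant analysis (BSA-seq) mapping of a single recessive locus
from two-pool sequencing data, with a built-in F2 pooled-sequencing
simulator so the whole analysis runs without external data.

**For whom:** plant geneticists (and anyone mapping a Mendelian trait)
who have — or want to prototype against — pooled short-read sequencing of
two phenotypic bulks from an F2 cross, called down to a two-sample VCF
with per-pool allelic depths.

## The method

A recessive qualitative trait segregates 3:1 in the F2. Sequencing a
mutant bulk and a wild-type bulk (30 individuals each, ~30× per pool)
gives per-site mutant-allele read fractions `f_gt` and `f_wt`. The scan
statistics are

- **ED** `= sqrt((f_gt-f_wt)^2 + ((1-f_gt)-(1-f_wt))^2) = sqrt(2)|f_gt-f_wt|`,
  averaged in 1 Mb windows stepped by 100 kb; windows above the
  genome-wide 99% quantile merge into candidate regions;
- **G** — the 2×2 likelihood-ratio statistic of the pool × allele read
  table — and **Δ-AF** `= f_gt - f_wt` as corroborating scans;
- **ideal-frequency distance** `= sqrt((f_gt-1)^2 + (f_wt-1/3)^2)`: at
  the causal site the mutant bulk is fixed (`f_gt = 1`) and the
  wild-type bulk segregates 1/3 hom-WT : 2/3 het, i.e. a 1:2 mutant:WT
  allele ratio (`f_wt = 1/3`). Coding/promoter sites in candidate
  regions are ranked by this distance and the nearest 5% reported.

Before scanning, sites are filtered: combined depth outside [25, 250],
homozygous-alternate in both pools (parent-vs-reference differences),
and heterozygous in both pools (no signal for a recessive trait).
Candidate coding indels are annotated for frameshift and premature-stop
consequences (original vs truncated protein length).

## Worked example

Simulate the default design (one 20 Mb chromosome, 2000 sites, causal
2-bp "AA" insertion at 12 Mb, bulks 30+30 at 30×) and run the scan:

```r
library(bsamap)
gmap <- genetic_map("chr1", 2e7)
cfg  <- sim_config(n_f2 = 240, n_sites = 2000, causal_chrom = "chr1",
                   causal_pos_bp = 1.2e7, seed = 1)
rep  <- run_pipeline(bsa_config(map = gmap, simulate = cfg,
                                region_classes = NULL, seed = 1))
rep$attrition
#>           filter removed retained
#> 1          depth       0     2000
#> 2 shared_hom_alt       0     2000
#> 3     shared_het     365     1635
rep$regions
#>   chrom    start      end n_windows peak_pos peak_stat threshold
#> 1  chr1 11800001 12900000         2 12300000  1.025214  1.021014
head(rep$candidates[, c("pos","f_wt","f_gt","ed","ed_ideal","rank")], 3)
#>        pos      f_wt f_gt       ed ed_ideal rank
#> 1 12455906 0.3333333    1 0.942809        0    1
#> 2 12567112 0.3333333    1 0.942809        0    2
#> 3 12614570 0.3333333    1 0.942809        0    3
```

The depth filter removes nothing (combined depth ~60× is inside
[25, 250]); 365 sites heterozygous in both pools drop out; the single
called region (11.8–12.9 Mb) contains the causal position, and the
top-ranked sites show the exact recessive pattern (`f_gt = 1`,
`f_wt = 1/3`, ED at its causal-expectation `sqrt(2)*2/3 = 0.943`,
ideal-distance 0).

On observed read counts — say a site where the mutant pool has 28/28
alt reads and the wild-type pool 10 alt / 21 ref:

```r
allele_frequency(0, 28)                 # f_gt = 1
allele_frequency(21, 10)                # f_wt = 0.32258
ideal_frequency_distance(10/31, 1)      # 0.01075  (near-ideal)
g_statistic(21, 10, 0, 28)              # 37.84
```

Real-data mode takes a VCF (+ optional GFF3/FASTA for region classes and
consequence annotation):

```r
cfg <- bsa_config(vcf = "pools.vcf", gff = "genes.gff3",
                  fasta = "genome.fa", out_dir = "bsa_out")
rep <- run_pipeline(cfg)
```

or from the shell via `inst/scripts/bsamap simulate|run`.

## Notes

The methods vignette (`vignettes/bsamap-methods.Rmd`) documents the
model assumptions, every tunable default, what the simulator does and
does not emulate, and a known localization limit of the single-
chromosome recovery experiment.
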