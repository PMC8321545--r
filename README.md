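# sgvscan

Genome scans for species-specific adaptation in recent adaptive radiations,
and classification of divergent alleles as **standing genetic variation
(SGV)** versus **new mutation**.

## The problem

In very young radiations — the canonical case being Lake Victoria's
haplochromine cichlids, where hundreds of species arose in ~10⁴ generations
— genome-wide differentiation between species is weak, so the handful of
strongly differentiated regions is where adaptation lives. Two questions
follow for each such region: *is it under selection in a particular
species?* and *how old are its divergent alleles?* Alleles older than the
radiation (often shared with other lakes' cichlids) point to selection on
standing variation; young alleles point to local sweeps from new mutations.

`sgvscan` implements the full toolchain for whoever wants to ask these
questions of a multi-sample VCF — or to study the behaviour of the methods
themselves on simulated truth:

* **variants** — VCF ingestion; site filters (biallelic / no-missing /
  indel / Hardy–Weinberg exact test, Levene's conditional distribution);
  plink-style LD pruning (50/5/0.1); per-individual inbreeding F.
* **winstats** — sliding-window (10 kb / 2 kb) nucleotide diversity π,
  Weir–Cockerham weighted F_ST (ratio of sums of the a, b, c variance
  components), absolute divergence d_XY = p_A(1−p_B)+p_B(1−p_A) per site,
  and smartpca-style genotype PCA.
* **scan** — highly differentiated regions (HDRs) as top-0.5% F_ST window
  outliers, merged; species-specificity labels; joint F_ST/d_XY sweep
  flags; candidate genes within 10-kb flanks; differentiated-SNP
  annotation (allele frequency ≥ 0.5; pairwise difference ≥ 0.6).
* **haploscan** — EHH / iHH / iHS on phased haplotypes with
  frequency-bin standardisation and two-sided 1% extreme calling.
* **sgv** — per-gene consensus alignments, neighbour-joining trees
  (Jukes–Cantor) with 100 column-bootstrap replicates, monophyly testing of
  the focal radiation at support ≥ 60 (non-monophyly with a nested
  outgroup-tier taxon ⇒ SGV, with origin depth from the deepest intruder),
  and a two-tailed Mann–Whitney comparison of per-gene maximum d_XY by
  origin class.
* **simgen** — a forward Wright–Fisher simulator (Rcpp) of a radiating
  species complex: recombination, infinite sites, hard sweeps conditioned
  on establishment, and ancient balanced polymorphisms driven to
  alternative fixation post-split (the SGV scenario), emitting VCF + BED +
  species map + newick + truth labels.
* **pipeline/CLI** — `run_pipeline()` orchestrates simulate → filter →
  winstats → PCA → scan → iHS → origin with plain-text intermediates, a
  JSON report and a log of every realised threshold.

## Worked example

The packaged demo world (20 regions × 600 kb; 5 de-novo sweeps in
*H. chilotes*, 5 SGV sweeps in *L. rufus*, 10 neutral):

```r
library(sgvscan)

cfg <- demo_pipeline_config("demo_run", seed = 5,
                            stages = c("simulate", "filter", "winstats",
                                       "scan"))
res <- run_pipeline(cfg)
cat(readLines("demo_run/log.txt"), sep = "\n")
```

printed, on this run:

```
simulate: 20 regions, 234967 variant sites
filter: 234967 -> 234967 sites (hwe_mode=per_species)
genome-wide weighted FST HChi_HSau = 0.107740
genome-wide weighted FST HChi_LRuf = 0.105883
genome-wide weighted FST HSau_LRuf = 0.116717
HDR threshold HChi_HSau: fst 0.371371, dxy 0.002143
HDR threshold HChi_LRuf: fst 0.569661, dxy 0.002772
HDR threshold HSau_LRuf: fst 0.562552, dxy 0.002967
scan: 17 HDRs, 10 candidate genes
```

Reading: background differentiation is weak (genome-wide weighted F_ST ≈
0.11, the regime of a very recent radiation), the per-pair HDR thresholds
are the empirical top-0.5% window cutoffs, and all ten truth sweeps land in
HDRs of a pair involving their target species — the ten candidate genes are
exactly the genes at the selected sites.

For allelic-origin work the preset switches the ancestral expansion to the
radiation onset (`expand_gen = "radiation"`), which keeps the focal stem
lineage-sorted (see the vignette on why one preset cannot serve both uses):

```r
cfg2 <- demo_pipeline_config("origin_run", seed = 5, n_neutral = 2,
                             n_de_novo = 5, n_sgv = 5, region_length = 8e4,
                             mu = 4e-6, n_focal = 400, n_deep = 40,
                             expand_gen = "radiation",
                             stages = c("simulate", "filter", "winstats",
                                        "scan", "origin"),
                             origin_genes = "all")
res2 <- run_pipeline(cfg2)
res2$origins
```

```
           gene       origin     depth support max_dxy
 gene_region001 new_mutation       n/a      90 0.00217
 gene_region002 new_mutation       n/a     100 0.00192
 gene_region003 new_mutation       n/a     100 0.00180
 gene_region004 new_mutation       n/a      97 0.00182
 gene_region005 new_mutation       n/a     100 0.00186
 gene_region006          SGV before_LT     100 0.00828
 gene_region007          SGV before_LT     100 0.01096
 gene_region008 new_mutation       n/a      97 0.00594
 gene_region009          SGV before_LT     100 0.00983
 gene_region010          SGV before_LT     100 0.00985
 gene_region011 new_mutation       n/a     100 0.00160
 gene_region012 new_mutation       n/a      83 0.00215
MW p = 0.00404; median max dXY: SGV 0.009842, new_mutation 0.00189
```

Regions 1–5 are truth de-novo sweeps, 6–10 truth SGV sweeps and 11–12
neutral: nine of the ten sweeps classify correctly (region008's deep signal
was lost to recombination on this seed), and SGV-class genes carry the
systematically higher maximum d_XY — their allele classes diverged before
the radiation — which the two-tailed Mann–Whitney comparison quantifies.

Lower-level entry points do the same work piecemeal: `read_vcf()`,
`filter_sites()`, `window_stats()`, `call_hdrs()`, `scan_species()`,
`build_gene_alignment()` → `nj_tree_with_bootstrap()` → `classify_origin()`
→ `compare_dxy_by_origin()`.

A CLI wrapper is installed at `inst/scripts/sgvscan`
(`sgvscan all --seed 5 --out demo_run`).

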