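---
title: "Methods: genome scans for sweeps and standing genetic variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome scans for sweeps and standing genetic variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sgvscan` implements the comparative-genomics toolchain used to dissect
species-specific adaptation in very recent adaptive radiations — the kind of
system exemplified by the Lake Victoria haplochromine cichlids, where
hundreds of species arose within roughly ten thousand generations and
genome-wide differentiation between species is weak ($F_{ST}$ of order
0.1–0.2). In such systems the small set of strongly differentiated genomic
regions is informative about selection, and the *age* of the divergent
haplotypes in those regions distinguishes two adaptive routes:

* **standing genetic variation (SGV)** — divergent allele classes that
  predate the radiation (sometimes predating splits between lakes), held in
  populations by balancing selection or structure and driven to alternative
  fixation when species specialised; and
* **new mutations** — alleles that arose within a species after its origin
  and swept locally.

The package covers: VCF ingestion and site filtering, sliding-window
differentiation statistics, empirical-outlier calling of highly
differentiated regions (HDRs), iHS haplotype scans, gene-tree-based
classification of allelic origins, and a forward simulator that generates
all of the above signal classes with known truth.

# Statistics

All windowed statistics use 10-kb windows advanced in 2-kb steps by default
and divide by the full window length, so invariant sites contribute zero.
Whether a windowed $d_{XY}$ should be normalised by accessible sites or by
physical length is a genuine convention choice; physical length is the
default here because simulated data have no inaccessible sites, and the
choice is isolated in one place. Truncated terminal windows are kept but
flagged, and quantile scans exclude windows shorter than half the nominal
length.

* Nucleotide diversity: site $\pi = 2 c_{\mathrm{ref}} c_{\mathrm{alt}} /
  (m(m-1))$ with $m$ the number of called alleles.
* Differentiation: the Weir–Cockerham (1984) estimator with variance
  components $a$ (among populations), $b$ (among individuals) and $c$
  (within individuals); window and genome-wide values are ratios of sums
  $\sum a / \sum (a+b+c)$, never means of ratios.
* Absolute divergence: site term $p_A(1-p_B) + p_B(1-p_A)$.

The Hardy–Weinberg filter is Levene's exact conditional test, summing the
probabilities of all heterozygote counts no more probable than the observed
one. By default it pools all individuals, exactly like a single `--hwe`
pass over a merged multi-species VCF. Pooling species violates the
random-mating assumption (Wahlund effect), so this filter *removes strongly
differentiated sites* — fully fixed differences between species are
flagged as heterozygote-deficient. That behaviour is faithful to common
practice, which is why the packaged demo switches to the per-species mode
(`hwe_mode = "per_species"`); with complete sweeps in the simulation the
pooled mode would delete precisely the signal under study.

LD pruning mirrors the common 50-SNP/5-SNP/0.1 windowed $r^2$ rule on
dosage (composite) correlations. The pair-resolution rule — drop the
lower-MAF member, ties drop the later-position SNP — is not standardised
across tools; determinism was prioritised over bit-compatibility with any
particular implementation.

# HDR calling

HDRs are empirical outliers: windows in the top 0.5% of a species pair's
window-$F_{ST}$ distribution, merged when overlapping or book-ended. The
threshold is the $k$-th largest value with $k = \lceil 0.005\,n \rceil$;
windows tied at the threshold are all included. Species specificity uses
any-base-pair overlap between the three pairwise HDR sets: an interval
found in the two pairs sharing species $S$ but not the third is
"$S$-specific". A putative sweep flag marks HDRs that also contain a
top-0.5% $d_{XY}$ window — regions differentiated in both allele frequency
and absolute sequence divergence. Genes are candidates when their interval
extended by a 10-kb flank touches an HDR.

# iHS scan

EHH for an allele class is the probability that two random carrier
haplotypes are identical from the core to the query position; iHH is the
trapezoidal integral of EHH against physical position, truncated when EHH
falls below 0.05 or across inter-SNP gaps larger than 20 kb (both defaults
of the common tooling; a genetic map is out of scope). The raw score
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$ is positive when ancestral-allele
haplotypes are unusually long. Cores whose EHH reaches the region edge (or
a gap) before decaying below the cutoff are skipped, as in the common
tooling — their truncated integrals otherwise produce spurious extreme
scores at contig boundaries. Scores are standardised to zero mean and
unit (population) variance within 50 derived-allele-frequency bins, and the
extreme flag is two-sided: the top 1% of $|$standardised iHS$|$. Whether
the upstream convention was one- or two-tailed is not recoverable from the
tool options alone; two-tailed is the default and the mass is
configurable.

# Allelic-origin classification

For each candidate gene a per-taxon consensus sequence (major allele per
site, ties to the reference) is assembled on reference coordinates;
columns with missing data are excised, mirroring the use of
deletion-free sites. Trees are neighbour-joining on Jukes–Cantor distances
with 100 column-bootstrap replicates; pairs with an undefined JC correction
fall back to the raw p-distance. NJ was chosen over full ML deliberately:
on ≤9 taxa the classification signal is carried by topology plus support,
which NJ reproduces at a small fraction of the cost, and the tree engine
sits behind a narrow interface (`nj_from_dist`) that an ML engine could
replace.

The classification rule: if the focal-radiation taxa are monophyletic with
bootstrap support ≥ 60, the divergent alleles are called `new_mutation`;
if a non-focal taxon is nested inside the smallest clade containing all
focal taxa, the call is `SGV`, with origin depth set by the deepest
supported intruding tier (Lake Tanganyika > riverine *H. burtoni* tier >
Lake Malawi). Which node's support the "≥ 60" rule should consult is
ambiguous in the source protocols; the decision here is the smallest clade
jointly containing the intruder and part (not all) of the focal taxa.
Finally, the distributions of per-gene maximum window $d_{XY}$ for the two
origin classes are compared with a two-tailed Mann–Whitney test (exact
enumeration when both classes have ≤ 8 genes, tie-corrected normal
approximation otherwise); under the SGV model the divergent classes have
been accumulating differences since before the radiation, so SGV genes
should show systematically higher maxima.

# The simulator and its stated world

The engine is a forward-time diploid Wright–Fisher model with Poisson
crossovers and infinite-sites mutations on continuous coordinates
(discretised to integer base pairs at output, collisions shifted by +1).
Forward simulation was chosen because the central scenario — an ancient
balanced polymorphism later driven to alternative fixation in different
descendant species — is awkward for coalescent machinery but trivial
forward in time. Lineages split by founder sampling from the parent; true
gamete phase is retained (statistical phasing is not reproduced).
Selection regimes are piecewise per lineage: neutral, overdominant
(heterozygote advantage, the balancing phase), or directional for either
allele. De-novo sweeps are conditioned on establishment by bounded retries
from a snapshot taken at the introduction generation.

All sizes are desk-scale: the spirit is to hold the population-scaled
compound parameters near realistic values while absolute sizes shrink by
orders of magnitude. The default radiation preset uses deep (pre-radiation
and outgroup) lineages of $N = 40$ diploids with tier splits every $3
\times 2N$ generations — deep enough that the outgroup tiers are mostly
lineage-sorted — and focal species of $N = 400$–500 with splits 90–130
generations before sampling, so that $T/2N \approx 0.1$ reproduces the
weak background differentiation (genome-wide weighted $F_{ST} \approx$
0.09–0.16, matching the range reported for real rocky-shore cichlid
pairs). Mutation rates are scaled up (defaults 2.5–4 × 10⁻⁶/bp/gen; the
biological rate is ~3.5 × 10⁻⁹) so that $\theta$ per site lands near
0.002–0.005 and 10-kb windows carry tens of SNPs. A generation time of 2
years is carried as metadata only.

Two modelling choices deserve emphasis:

* **Recombination suppression at SGV loci.** Ancient balanced haplotypes
  of the kind this scenario emulates are, empirically, held together by
  local recombination suppression (the real loci show divergent haplotypes
  spanning 30–50 kb). Desk-scale balancing phases cannot retain a deeply
  divergent haplotype class against free recombination, so `sgv_sweep`
  scenarios thin crossovers by a factor 0.02 within ±5 kb of the selected
  site. This is a statement about the biology being emulated, not a tuning
  knob.
* **Sweep-type segregation in the demo.** A one-sided hard sweep
  (target species fixes one haplotype, the partner keeps its diversity)
  physically caps window $F_{ST}$ near 0.5 under the Weir–Cockerham
  estimator, whereas differential fixation of anciently diverged classes
  approaches 1. A 20-region demo compresses sweep density about a
  thousandfold relative to a real genome, so if both sweep types loaded
  the same species pair, the tiny top-0.5% window budget would be consumed
  entirely by SGV windows. The demo therefore assigns all de-novo sweeps
  to *H. chilotes* and all SGV sweeps to *L. rufus* (which also mirrors
  the real-data observation that the generalist species' HDRs are
  dominated by high-$d_{XY}$ SGV signals), and uses 600-kb regions so each
  pair has roughly 3,000 windows.

## What a green test establishes — and what it does not

The generator emulates: biallelic SNPs with true phase, weak background
differentiation with realistic $F_{ST}$/$d_{XY}$/π scales, hard sweeps,
trans-radiation balanced polymorphisms, outgroup tiers with mostly sorted
species trees, and simple two-exon gene models at selected sites. It does
not emulate: missing data patterns, genotyping error, indels and repeats,
gene flow/introgression after splits, varying recombination maps beyond
the SGV suppression window, chromosome-scale linkage, or assembly
artefacts. Green acceptance tests therefore establish algorithmic
correctness and statistical behaviour under the stated model, not
robustness to real-data pathology (the filter chain addresses some of the
latter and is tested on constructed corner cases).

# Numerical and procedural choices

* Empirical quantiles are "top-$k$ with ties" ($k = \lceil q\,n \rceil$,
  computed with a $10^{-9}$ guard against floating-point error in
  $q \times n$); this makes outlier sets deterministic and reproducible.
* iHS standardisation uses population (not sample) moments within bins, so
  a two-score bin standardises to exactly ±1.
* iHH integration adds the final trapezoid that crosses the 0.05 cutoff,
  then stops; cores with a zero-length side integral are skipped.
* HWE p-values are computed in log space and memoised over distinct
  genotype-count triples when filtering whole matrices.
* The engine's RNG is a seeded Mersenne Twister; runs are byte-identical
  for a fixed seed on a given platform/compiler (the C++ standard fixes
  the generator but not the distribution algorithms, so cross-platform
  bit-identity is not promised).
* Monomorphic HWE sites return p = 1; all-missing windows are NA, not 0;
  PCA of a constant matrix returns all-zero coordinates.

# Known limitations

* The origin classifier assumes the deep species tree is known and mostly
  sorted; massive incomplete lineage sorting in the outgroup tiers would
  blur depth labels (though consensus-distance trees are robust to
  moderate ILS because expected distances respect the species tree).
* One-sided de-novo sweeps are intrinsically hard to catch with a pure
  $F_{ST}$ top-quantile rule at desk-scale sweep densities (see above);
  iHS is the appropriate detector for incomplete or one-sided sweeps.
* The Mann–Whitney comparison inherits candidate-gene selection bias: with
  HDR-gated gene selection the de-novo class can be nearly empty. The
  pipeline exposes `origin_genes = "all"` for studies of the classifier
  itself.
* `vcf` ingestion trusts GT; depth/quality fields, when absent (as in
  simulated data), make the read-level filter rules no-ops.
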