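## Genotype container, VCF ingestion and the site-filter chain.

#' Diploid genotype matrix with per-site metadata
#'
#' Sites x individuals alternate-allele dosages (0/1/2, NA = missing) with
#' contig, 1-based position, ref/alt alleles, per-site flags, a sample-to-
#' species map and, when phase is known, the underlying haplotype alleles
#' (two columns per individual).
#'
#' @param contig,pos,ref,alt per-site metadata vectors (positions must be
#'   strictly increasing within each contig).
#' @param hap optional sites x (2 * individuals) 0/1 haplotype matrix.
#' @param dos optional sites x individuals dosage matrix; derived from `hap`
#'   when omitted.
#' @param samples character vector of sample names (column order).
#' @param species named character vector mapping sample -> species.
#' @param hap_sample for phased data, sample name of each haplotype column.
#' @param multiallelic,indel optional per-site logical flags.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(contig, pos, ref, alt, hap = NULL, dos = NULL,
                            samples, species, hap_sample = NULL,
                            multiallelic = NULL, indel = NULL) {
  n <- length(pos)
  stopifnot(length(contig) == n, length(ref) == n, length(alt) == n)
  if (is.null(dos)) {
    if (is.null(hap)) stop("need hap or dos")
    if (is.null(hap_sample)) hap_sample <- rep(samples, each = 2)
    dos <- hap[, seq(1, ncol(hap), by = 2), drop = FALSE] +
      hap[, seq(2, ncol(hap), by = 2), drop = FALSE]
    colnames(dos) <- hap_sample[seq(1, length(hap_sample), by = 2)]
    dos <- dos[, samples, drop = FALSE]
  }
  if (!all(samples %in% names(species)))
    stop("sample missing from species map: ",
         paste(setdiff(samples, names(species)), collapse = ", "))
  for (ct in unique(contig)) {
    p <- pos[contig == ct]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions not strictly increasing on contig ", ct)
  }
  if (is.null(multiallelic)) multiallelic <- rep(FALSE, n)
  if (is.null(indel)) indel <- rep(FALSE, n)
  structure(list(contig = as.character(contig), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 hap = hap, dos = dos, samples = samples,
                 species = species[samples], hap_sample = hap_sample,
                 phased = !is.null(hap),
                 multiallelic = as.logical(multiallelic),
                 indel = as.logical(indel)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d individuals (%s), %d contig(s)\n",
              length(x$pos), length(x$samples),
              if (x$phased) "phased" else "unphased",
              length(unique(x$contig))))
  cat("species:", paste(sprintf("%s (%d)", names(table(x$species)),
                                table(x$species)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm a [genotype_matrix].
#' @export
n_sites <- function(gm) length(gm$pos)

#' Subset a genotype matrix by site index and/or samples
#' @param gm a [genotype_matrix].
#' @param sites integer or logical site index.
#' @param samples character vector of samples to keep.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_along(gm$pos)
  out <- gm
  out$contig <- gm$contig[sites]
  out$pos <- gm$pos[sites]
  out$ref <- gm$ref[sites]
  out$alt <- gm$alt[sites]
  out$multiallelic <- gm$multiallelic[sites]
  out$indel <- gm$indel[sites]
  out$dos <- gm$dos[sites, , drop = FALSE]
  if (!is.null(gm$hap)) out$hap <- gm$hap[sites, , drop = FALSE]
  if (!is.null(samples)) {
    stopifnot(all(samples %in% gm$samples))
    out$dos <- out$dos[, samples, drop = FALSE]
    if (!is.null(out$hap)) {
      keep <- gm$hap_sample %in% samples
      out$hap <- out$hap[, keep, drop = FALSE]
      out$hap_sample <- gm$hap_sample[keep]
    }
    out$samples <- samples
    out$species <- gm$species[samples]
  }
  out
}

#' Combine genotype matrices over disjoint contigs (same samples)
#' @param ... genotype_matrix objects.
#' @export
rbind_genotype_matrix <- function(...) {
  gms <- list(...)
  stopifnot(length(gms) >= 1)
  base <- gms[[1]]
  for (g in gms[-1]) stopifnot(identical(g$samples, base$samples))
  out <- base
  out$contig <- unlist(lapply(gms, `[[`, "contig"))
  out$pos <- unlist(lapply(gms, `[[`, "pos"))
  out$ref <- unlist(lapply(gms, `[[`, "ref"))
  out$alt <- unlist(lapply(gms, `[[`, "alt"))
  out$multiallelic <- unlist(lapply(gms, `[[`, "multiallelic"))
  out$indel <- unlist(lapply(gms, `[[`, "indel"))
  out$dos <- do.call(rbind, lapply(gms, `[[`, "dos"))
  if (!is.null(base$hap)) out$hap <- do.call(rbind, lapply(gms, `[[`, "hap"))
  out
}

## ---------------------------------------------------------------- VCF I/O

#' Read a VCF into a genotype matrix
#'
#' Multiallelic records are retained but flagged; indel records are flagged
#' by allele length.  Dosage is the count of non-reference alleles.  Phase is
#' taken from the GT separator and the haplotype matrix is populated only
#' when every called genotype is phased.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param species_map named character vector (sample -> species), a
#'   two-column data.frame, or the path of a headerless two-column TSV.
#' @return a [genotype_matrix].
#' @export
read_vcf <- function(path, species_map) {
  species <- .as_species_map(species_map)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  missing <- setdiff(samples, names(species))
  if (length(missing))
    stop("sample missing from species map: ", paste(missing, collapse = ", "))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altl)
  alt <- vapply(seq_along(nalt), function(i)
    paste(as.character(altl[[i]]), collapse = ","), "")
  multiallelic <- nalt > 1
  indel <- nchar(ref) > 1 |
    vapply(seq_along(nalt), function(i)
      any(nchar(as.character(altl[[i]])) != 1), TRUE)

  phased <- all(grepl("\\|", gt[gt != "./." & gt != ".|." & gt != "."]))
  parse_col <- function(g) {
    parts <- strsplit(g, "[/|]")
    vapply(parts, function(p) {
      if (any(p == ".")) NA_integer_ else sum(as.integer(p) > 0)
    }, 0L)
  }
  dos <- vapply(seq_len(ncol(gt)), function(j) parse_col(gt[, j]),
                integer(nrow(gt)))
  dos <- matrix(dos, nrow = nrow(gt), dimnames = list(NULL, samples))
  hap <- NULL
  hap_sample <- NULL
  if (phased && nrow(gt)) {
    a1 <- matrix(as.integer(sub("\\|.*", "", gt) != "0" &
                              sub("\\|.*", "", gt) != "."), nrow = nrow(gt))
    a2 <- matrix(as.integer(sub(".*\\|", "", gt) != "0" &
                              sub(".*\\|", "", gt) != "."), nrow = nrow(gt))
    a1[is.na(dos)] <- NA_integer_
    a2[is.na(dos)] <- NA_integer_
    hap <- matrix(NA_integer_, nrow(gt), 2 * ncol(gt))
    hap[, seq(1, ncol(hap), 2)] <- a1
    hap[, seq(2, ncol(hap), 2)] <- a2
    hap_sample <- rep(samples, each = 2)
  }
  gm <- genotype_matrix(contig = as.character(GenomicRanges::seqnames(rr)),
                        pos = GenomicRanges::start(rr), ref = ref, alt = alt,
                        hap = hap, dos = dos, samples = samples,
                        species = species, hap_sample = hap_sample,
                        multiallelic = multiallelic, indel = indel)
  sl <- GenomeInfoDb::seqlengths(rr)
  if (length(sl) && !all(is.na(sl)))
    attr(gm, "contig_lengths") <- sl[!is.na(sl)]
  gm
}

.as_species_map <- function(species_map) {
  if (is.character(species_map) && length(species_map) == 1 &&
      file.exists(species_map)) {
    df <- read.table(species_map, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE)
    return(setNames(df[[2]], df[[1]]))
  }
  if (is.data.frame(species_map))
    return(setNames(species_map[[2]], species_map[[1]]))
  if (is.null(names(species_map))) stop("species map must be named")
  species_map
}

#' Write a genotype matrix as VCF v4.2
#' @param gm a [genotype_matrix].
#' @param path output file.
#' @param contig_lengths optional named vector for contig header lines.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sgvscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (gm$phased) {
    a1 <- gm$hap[, seq(1, ncol(gm$hap), 2), drop = FALSE]
    a2 <- gm$hap[, seq(2, ncol(gm$hap), 2), drop = FALSE]
    gts <- matrix(paste0(a1, "|", a2), nrow = nrow(a1))
    gts[is.na(a1) | is.na(a2)] <- ".|."
  } else {
    gts <- matrix(c("0/0", "0/1", "1/1")[gm$dos + 1L], nrow = nrow(gm$dos))
    gts[is.na(gm$dos)] <- "./."
  }
  cols <- c(list(gm$contig, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                 "GT"),
            lapply(seq_len(ncol(gts)), function(j) gts[, j]))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

## ------------------------------------------------------------ gene models

#' Write gene models as BED6 (name = "gene;feature")
#' @param models data.frame with columns gene, contig, start, end, feature.
#' @param path output file.
#' @export
write_gene_models <- function(models, path) {
  bed <- data.frame(models$contig, models$start, models$end,
                    paste(models$gene, models$feature, sep = ";"), 0L, "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED (name = "gene" or "gene;feature") or GFF3
#' @param path input file; format chosen by extension.
#' @return data.frame(gene, contig, start, end, feature); coordinates 0-based
#'   half-open.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    g <- rtracklayer::import(path)
    df <- data.frame(
      gene = as.character(g$ID %||% g$Name),
      contig = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g),
      feature = as.character(g$type), stringsAsFactors = FALSE)
    df$feature[df$feature %in% c("CDS")] <- "exon"
    return(df)
  }
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  name <- strsplit(df[[4]], ";", fixed = TRUE)
  data.frame(gene = vapply(name, `[`, "", 1),
             contig = df[[1]], start = df[[2]], end = df[[3]],
             feature = vapply(name, function(x)
               if (length(x) > 1) x[2] else "gene", ""),
             stringsAsFactors = FALSE)
}

## ------------------------------------------------------------- site filter

#' Site-filter configuration
#'
#' Defaults mirror a strict merged-VCF cleaning pass: biallelic SNPs only, no
#' missing genotypes, indels removed, Hardy-Weinberg exact p >= 0.001.
#' `hwe_mode` selects whether the HWE test pools all individuals (a single
#' pass over the merged VCF; note that this removes strongly differentiated
#' sites through the Wahlund effect) or is applied within each species.
#' `maf_min` (minor allele frequency, pooled) is off by default and is meant
#' for the structure-analysis path (set it to 0.05 there).
#'
#' @param require_biallelic drop multiallelic records.
#' @param max_missing_fraction maximum fraction of missing genotypes per site.
#' @param drop_indels drop records flagged as indels.
#' @param hwe_alpha significance level of the HWE exact test (NA disables).
#' @param hwe_mode `"pooled"` or `"per_species"`.
#' @param maf_min minimum pooled minor allele frequency (0 disables).
#' @export
filter_config <- function(require_biallelic = TRUE, max_missing_fraction = 0,
                          drop_indels = TRUE, hwe_alpha = 0.001,
                          hwe_mode = c("pooled", "per_species"),
                          maf_min = 0) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1,
            is.na(hwe_alpha) || (hwe_alpha >= 0 && hwe_alpha <= 1),
            maf_min >= 0, maf_min <= 1)
  structure(list(require_biallelic = require_biallelic,
                 max_missing_fraction = max_missing_fraction,
                 drop_indels = drop_indels, hwe_alpha = hwe_alpha,
                 hwe_mode = match.arg(hwe_mode), maf_min = maf_min),
            class = "filter_config")
}

#' Apply the site-filter chain
#'
#' Rules are applied in order biallelic, indel, missingness, HWE, MAF; the
#' log records the first rule that removed each dropped site.
#'
#' @param gm a [genotype_matrix].
#' @param cfg a [filter_config()].
#' @return list with elements `genotypes` (filtered matrix) and `log`
#'   (data.frame contig, pos, rule for dropped sites).
#' @export
filter_sites <- function(gm, cfg = filter_config()) {
  n <- n_sites(gm)
  rule <- rep(NA_character_, n)
  mark <- function(drop, name) {
    newly <- drop & is.na(rule)
    rule[newly] <<- name
  }
  if (isTRUE(cfg$require_biallelic)) mark(gm$multiallelic, "multiallelic")
  if (isTRUE(cfg$drop_indels)) mark(gm$indel, "indel")
  miss_frac <- rowMeans(is.na(gm$dos))
  mark(miss_frac > cfg$max_missing_fraction, "missing")
  if (!is.na(cfg$hwe_alpha) && cfg$hwe_alpha > 0) {
    live <- is.na(rule)
    if (any(live)) {
      if (cfg$hwe_mode == "pooled") {
        p <- .hwe_pvals(gm$dos[live, , drop = FALSE])
        mark(replace(logical(n), which(live), p < cfg$hwe_alpha), "hwe")
      } else {
        pmin_sp <- rep(1, sum(live))
        for (sp in unique(gm$species)) {
          cols <- gm$samples[gm$species == sp]
          p <- .hwe_pvals(gm$dos[live, cols, drop = FALSE])
          pmin_sp <- pmin(pmin_sp, p)
        }
        mark(replace(logical(n), which(live), pmin_sp < cfg$hwe_alpha), "hwe")
      }
    }
  }
  if (cfg$maf_min > 0) {
    p <- rowMeans(gm$dos, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    mark(maf < cfg$maf_min, "maf")
  }
  keep <- is.na(rule)
  list(genotypes = gm_subset(gm, keep),
       log = data.frame(contig = gm$contig[!keep], pos = gm$pos[!keep],
                        rule = rule[!keep], stringsAsFactors = FALSE))
}

## Vectorised HWE exact p-values for a dosage matrix (rows = sites),
## memoised over distinct genotype-count triples.
.hwe_pvals <- function(dos) {
  nAA <- rowSums(dos == 0, na.rm = TRUE)
  nAa <- rowSums(dos == 1, na.rm = TRUE)
  naa <- rowSums(dos == 2, na.rm = TRUE)
  key <- paste(nAA, nAa, naa)
  first <- !duplicated(key)
  pu <- vapply(which(first), function(i)
    hwe_exact_test(nAA[i], nAa[i], naa[i]), 0)
  pu[match(key, key[first])]
}

#' Hardy-Weinberg exact test (Levene's conditional distribution)
#'
#' Two-sided exact test: the p-value is the total probability, under the
#' exact conditional (Levene) distribution of heterozygote counts given the
#' allele counts, of all outcomes no more probable than the observed one.
#' Monomorphic sites return 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("no genotypes")
  nr <- 2 * min(n_hom_ref, n_hom_alt) + n_het  # minor allele count
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  ## log Levene probability of h heterozygotes given n diploids, nr minor
  ## alleles: P(h) = n! nr! (2n-nr)! 2^h / [ (2n)! h! ((nr-h)/2)! ((2n-nr-h)/2 - (n - ...))! ]
  logp <- vapply(hets, function(h) {
    hom_min <- (nr - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_min + 1) - lgamma(hom_maj + 1) +
      h * log(2) + lgamma(nr + 1) + lgamma(2 * n - nr + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

## -------------------------------------------------------------- LD pruning

#' Prune SNPs by pairwise linkage disequilibrium
#'
#' Sliding windows of `window_snps` SNPs advanced by `step_snps`; within a
#' window, pairs with squared dosage correlation above `r2_max` are resolved
#' by removing the member with the lower (pooled) minor allele frequency,
#' ties by removing the later-position SNP.  Deterministic for fixed input.
#' Windows never span contig boundaries.
#'
#' @param gm a [genotype_matrix] (apply any MAF filter first).
#' @param window_snps,step_snps,r2_max pruning parameters.
#' @return integer vector of retained site indices.
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.1) {
  keep <- rep(TRUE, n_sites(gm))
  p <- rowMeans(gm$dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  for (ct in unique(gm$contig)) {
    idx_all <- which(gm$contig == ct)
    nct <- length(idx_all)
    starts <- seq(1, max(1, nct), by = step_snps)
    for (s in starts) {
      win <- idx_all[s:min(s + window_snps - 1, nct)]
      live <- win[keep[win]]
      if (length(live) < 2) next
      cc <- suppressWarnings(
        stats::cor(gm$dos[live, , drop = FALSE] |> t(),
                   use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      present <- rep(TRUE, length(live))
      for (i in seq_len(length(live) - 1)) {
        if (!present[i]) next
        for (j in seq((i + 1), length(live))) {
          if (!present[j]) next
          if (r2[i, j] > r2_max) {
            gi <- live[i]; gj <- live[j]
            drop_j <- maf[gj] < maf[gi] ||
              (maf[gj] == maf[gi])  # tie: drop later-position SNP
            if (drop_j) present[j] <- FALSE else {
              present[i] <- FALSE
              break
            }
          }
        }
      }
      keep[live[!present]] <- FALSE
      if (s + window_snps - 1 >= nct) break
    }
  }
  which(keep)
}

## --------------------------------------------------- inbreeding coefficient

#' Per-individual inbreeding coefficient (method-of-moments F)
#'
#' F = (O_hom - E_hom) / (L - E_hom), with the per-site expected homozygosity
#' 1 - 2p(1-p) m/(m-1) computed from the pooled allele frequency p and the
#' pooled called allele count m.  Individuals with no informative sites
#' (L = E_hom) are reported as NA.
#'
#' @param gm a [genotype_matrix] (>= 2 individuals).
#' @return named numeric vector of F per individual.
#' @export
inbreeding_coefficient <- function(gm) {
  if (length(gm$samples) < 2) stop("need >= 2 individuals")
  dos <- gm$dos
  called <- !is.na(dos)
  m <- 2 * rowSums(called)
  p <- rowSums(dos, na.rm = TRUE) / m
  e_hom <- ifelse(m > 1, 1 - 2 * p * (1 - p) * m / (m - 1), NA_real_)
  ok <- !is.na(e_hom)
  vapply(seq_along(gm$samples), function(j) {
    use <- ok & called[, j]
    L <- sum(use)
    if (L == 0) return(NA_real_)
    E <- sum(e_hom[use])
    O <- sum(dos[use, j] != 1)
    if (abs(L - E) < 1e-12) return(NA_real_)
    (O - E) / (L - E)
  }, 0) |> setNames(gm$samples)
}

#' Per-species alternate-allele frequencies
#' @param gm a [genotype_matrix].
#' @param species species to compute for (default: all).
#' @return matrix sites x species of alt-allele frequencies.
#' @export
allele_freq <- function(gm, species = unique(gm$species)) {
  out <- vapply(species, function(sp) {
    cols <- gm$samples[gm$species == sp]
    d <- gm$dos[, cols, drop = FALSE]
    rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
  }, numeric(n_sites(gm)))
  matrix(out, nrow = n_sites(gm), dimnames = list(NULL, species))
}
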