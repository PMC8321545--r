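## Highly differentiated region (HDR) calling from window statistics,
## species-specificity assignment, joint FST/dXY sweep flags, gene mapping
## with flanks and differentiated-SNP annotation.

.pair_key <- function(pair) if (length(pair) == 2) paste(pair, collapse = "_") else pair

.pair_species <- function(pair_key) strsplit(pair_key, "_", fixed = TRUE)[[1]]

## Empirical "top fraction" threshold: the k-th largest value with
## k = ceiling(frac * n); windows tied at the threshold are all selected.
.top_threshold <- function(x, frac) {
  x <- x[!is.na(x)]
  k <- max(1, ceiling(frac * length(x) - 1e-9))  # guard fp error in frac * n
  sort(x, decreasing = TRUE)[k]
}

## Valid windows for quantile scans: stat present and window length at least
## half the nominal (full) window length.
.valid_windows <- function(stats, col) {
  len <- stats$end - stats$start
  nominal <- max(len[stats$full], len)
  !is.na(stats[[col]]) & len >= 0.5 * nominal
}

#' Call highly differentiated regions for one species pair
#'
#' Windows whose FST lies in the empirical top `1 - quantile` of the pair's
#' distribution (ties at the threshold included) are merged into maximal
#' regions when they overlap or are book-ended.
#'
#' @param stats a [window_stats()] table.
#' @param pair species pair, as `c("A", "B")` or `"A_B"` matching the stat
#'   columns.
#' @param quantile outlier quantile (default 0.995, i.e. the top 0.5%).
#' @return data.frame(contig, start, end, pair, threshold, peak_fst,
#'   peak_dxy, n_windows); attribute `threshold` holds the realised cutoff.
#' @export
call_hdrs <- function(stats, pair, quantile = 0.995) {
  key <- .pair_key(pair)
  col <- paste0("fst_", key)
  if (!col %in% names(stats)) stop("no FST column for pair ", key)
  if (all(is.na(stats[[col]]))) stop("all-missing FST column for pair ", key)
  valid <- .valid_windows(stats, col)
  if (sum(valid) < 200)
    warning("only ", sum(valid), " valid windows; outlier threshold unstable")
  thr <- .top_threshold(stats[[col]][valid], 1 - quantile)
  out_idx <- which(valid & stats[[col]] >= thr)
  dxy_col <- paste0("dxy_", key)
  regions <- .merge_windows(stats, out_idx, col, dxy_col)
  if (nrow(regions)) {
    regions$pair <- key
    regions$threshold <- thr
  }
  attr(regions, "threshold") <- thr
  attr(regions, "outlier_windows") <- out_idx
  regions
}

## Merge outlier windows (overlapping or book-ended) into maximal regions.
.merge_windows <- function(stats, idx, fst_col, dxy_col) {
  if (!length(idx))
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), peak_fst = numeric(),
                      peak_dxy = numeric(), n_windows = integer()))
  gr <- GenomicRanges::GRanges(stats$contig[idx],
                               IRanges::IRanges(stats$start[idx] + 1,
                                                stats$end[idx]))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(ov)
  fst <- stats[[fst_col]][idx]
  dxy <- if (dxy_col %in% names(stats)) stats[[dxy_col]][idx] else
    rep(NA_real_, length(idx))
  data.frame(
    contig = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    peak_fst = as.numeric(tapply(fst, grp, max)),
    peak_dxy = as.numeric(tapply(dxy, grp, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))),
    n_windows = as.integer(table(grp)),
    stringsAsFactors = FALSE)
}

#' Flag HDRs showing the joint FST/dXY sweep signature
#'
#' A region is flagged as a putative sweep if at least one of its member
#' outlier windows also lies in the top `1 - dxy_quantile` of the pair's
#' window dXY distribution.
#'
#' @param stats a [window_stats()] table.
#' @param hdrs output of [call_hdrs()] for the same pair.
#' @param pair the species pair.
#' @param dxy_quantile outlier quantile for dXY (default 0.995).
#' @return `hdrs` with a logical `sweep` column; attribute `dxy_threshold`.
#' @export
sweep_flag <- function(stats, hdrs, pair, dxy_quantile = 0.995) {
  key <- .pair_key(pair)
  fst_col <- paste0("fst_", key)
  dxy_col <- paste0("dxy_", key)
  if (!dxy_col %in% names(stats)) stop("no dXY column for pair ", key)
  valid <- .valid_windows(stats, dxy_col)
  dthr <- .top_threshold(stats[[dxy_col]][valid], 1 - dxy_quantile)
  out_idx <- attr(hdrs, "outlier_windows")
  hdrs$sweep <- FALSE
  if (nrow(hdrs) && length(out_idx)) {
    joint <- out_idx[!is.na(stats[[dxy_col]][out_idx]) &
                       stats[[dxy_col]][out_idx] >= dthr]
    if (length(joint)) {
      lv <- union(unique(stats$contig[joint]), unique(hdrs$contig))
      wgr <- GenomicRanges::GRanges(factor(stats$contig[joint], lv),
                                    IRanges::IRanges(stats$start[joint] + 1,
                                                     stats$end[joint]))
      rgr <- GenomicRanges::GRanges(factor(hdrs$contig, lv),
                                    IRanges::IRanges(hdrs$start + 1,
                                                     hdrs$end))
      hit <- unique(S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(wgr, rgr)))
      hdrs$sweep[hit] <- TRUE
    }
  }
  attr(hdrs, "dxy_threshold") <- dthr
  hdrs
}

#' Assign species-specificity labels across the three pair-wise HDR sets
#'
#' An HDR interval present (any-bp overlap) in the two pairs sharing species
#' S and absent from the third pair is labelled `"<S>_specific"`; present in
#' exactly one pair, `"pair_only"`; in all three, `"multi_pair"`.
#'
#' @param hdr_list named list of HDR data.frames, names `"A_B"` for the three
#'   pairs of three species.
#' @return the same list with a `label` column added to each element.
#' @export
assign_specificity <- function(hdr_list) {
  stopifnot(length(hdr_list) == 3, !is.null(names(hdr_list)))
  keys <- names(hdr_list)
  lv_all <- unique(unlist(lapply(hdr_list, function(d) d$contig)))
  as_gr <- function(df)
    GenomicRanges::GRanges(factor(df$contig, lv_all),
                           IRanges::IRanges(df$start + 1, df$end))
  for (key in keys) {
    df <- hdr_list[[key]]
    if (!nrow(df)) {
      df$label <- character(0)
      hdr_list[[key]] <- df
      next
    }
    gr <- as_gr(df)
    others <- setdiff(keys, key)
    hits <- vapply(others, function(o) {
      odf <- hdr_list[[o]]
      if (!nrow(odf)) return(rep(FALSE, nrow(df)))
      GenomicRanges::countOverlaps(gr, as_gr(odf)) > 0
    }, logical(nrow(df)))
    hits <- matrix(hits, nrow = nrow(df))
    df$label <- vapply(seq_len(nrow(df)), function(i) {
      inother <- others[hits[i, ]]
      if (length(inother) == 0) return("pair_only")
      if (length(inother) == 2) return("multi_pair")
      shared <- intersect(.pair_species(key), .pair_species(inother))
      paste0(shared, "_specific")
    }, "")
    hdr_list[[key]] <- df
  }
  hdr_list
}

#' Map gene models to HDRs with flanking regions
#'
#' A gene is a candidate iff its interval expanded by `flank` bp overlaps an
#' HDR.  The maximum window dXY over windows overlapping the gene itself is
#' recorded (over all dXY columns present, or the HDR's own pair).
#'
#' @param hdrs data.frame of HDRs (possibly several pairs concatenated; must
#'   have contig/start/end and pair columns).
#' @param genes gene-model data.frame ([read_gene_models()] format); only
#'   `feature == "gene"` rows are used.
#' @param stats optional [window_stats()] table used to record per-gene
#'   maximum dXY.
#' @param flank flank size in bp (default 10 kb).
#' @param contigs optional character vector of known contigs; genes on other
#'   contigs are skipped with a warning.
#' @return data.frame of candidate genes (gene, contig, start, end, pairs,
#'   max_dxy).
#' @export
map_genes_to_hdrs <- function(hdrs, genes, stats = NULL, flank = 10000,
                              contigs = NULL) {
  g <- genes[genes$feature == "gene", , drop = FALSE]
  if (!is.null(contigs)) {
    unknown <- !g$contig %in% contigs
    if (any(unknown)) {
      warning("skipping ", sum(unknown), " gene(s) on unknown contig(s): ",
              paste(unique(g$contig[unknown]), collapse = ", "))
      g <- g[!unknown, , drop = FALSE]
    }
  }
  if (!nrow(g) || !nrow(hdrs))
    return(data.frame(gene = character(), contig = character(),
                      start = numeric(), end = numeric(), pairs = character(),
                      max_dxy = numeric()))
  lv <- union(unique(g$contig), unique(hdrs$contig))
  ggr <- GenomicRanges::GRanges(
    factor(g$contig, lv),
    IRanges::IRanges(pmax(0, g$start - flank) + 1, g$end + flank))
  hgr <- GenomicRanges::GRanges(factor(hdrs$contig, lv),
                                IRanges::IRanges(hdrs$start + 1, hdrs$end))
  ov <- GenomicRanges::findOverlaps(ggr, hgr)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  cand_idx <- sort(unique(qh))
  if (!length(cand_idx)) return(map_genes_to_hdrs(hdrs[0, ], g))
  pairs <- vapply(cand_idx, function(i)
    paste(sort(unique(hdrs$pair[sh[qh == i]])), collapse = ","), "")
  out <- data.frame(gene = g$gene[cand_idx], contig = g$contig[cand_idx],
                    start = g$start[cand_idx], end = g$end[cand_idx],
                    pairs = pairs, max_dxy = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(stats)) {
    dxy_cols <- grep("^dxy_", names(stats), value = TRUE)
    lv2 <- union(unique(stats$contig), unique(out$contig))
    wgr <- GenomicRanges::GRanges(factor(stats$contig, lv2),
                                  IRanges::IRanges(stats$start + 1,
                                                   stats$end))
    body <- GenomicRanges::GRanges(factor(out$contig, lv2),
                                   IRanges::IRanges(out$start + 1, out$end))
    wo <- GenomicRanges::findOverlaps(body, wgr)
    for (i in seq_len(nrow(out))) {
      wins <- S4Vectors::subjectHits(wo)[S4Vectors::queryHits(wo) == i]
      if (length(wins)) {
        vals <- unlist(stats[wins, dxy_cols, drop = FALSE])
        if (any(!is.na(vals))) out$max_dxy[i] <- max(vals, na.rm = TRUE)
      }
    }
  }
  out
}

#' Annotate SNPs in candidate genes by genic region and differentiation
#'
#' Every SNP within `flank` bp of a candidate gene is labelled by genic
#' region (exon/UTR/intron/flank from the gene models).  A SNP is flagged
#' `differentiated` when its within-species alternate-allele frequency is at
#' least `diff_freq` in some species, and `large_diff` when the absolute
#' frequency difference for the focal pair is at least `large_diff_freq`.
#'
#' @param gm a [genotype_matrix].
#' @param candidates candidate genes from [map_genes_to_hdrs()].
#' @param gene_models full gene-model table (with exon/UTR rows).
#' @param pair optional focal species pair for the large-difference flag
#'   (default: the maximum pairwise difference over all species).
#' @param diff_freq,large_diff_freq flag thresholds (defaults 0.5 and 0.6).
#' @param flank flank size in bp.
#' @return list: `snps` (per-SNP annotations) and `genes` (per-gene summary
#'   with `coding_diff`, whether any exonic SNP is differentiated).
#' @export
annotate_differentiated_snps <- function(gm, candidates, gene_models,
                                         pair = NULL, diff_freq = 0.5,
                                         large_diff_freq = 0.6,
                                         flank = 10000) {
  freqs <- allele_freq(gm)
  if (!is.null(pair)) {
    sp <- .pair_species(.pair_key(pair))
    dif <- abs(freqs[, sp[1]] - freqs[, sp[2]])
  } else if (ncol(freqs) > 1) {
    rng <- apply(freqs, 1, range, na.rm = TRUE)
    dif <- rng[2, ] - rng[1, ]
  } else dif <- rep(0, n_sites(gm))
  snp_rows <- list()
  for (i in seq_len(nrow(candidates))) {
    gene <- candidates$gene[i]
    ct <- candidates$contig[i]
    g0 <- candidates$start[i]
    g1 <- candidates$end[i]
    in_range <- which(gm$contig == ct & gm$pos > g0 - flank &
                        gm$pos <= g1 + flank)
    if (!length(in_range)) next
    feats <- gene_models[gene_models$gene == gene &
                           gene_models$feature != "gene", , drop = FALSE]
    region <- vapply(in_range, function(s) {
      pos0 <- gm$pos[s] - 1  # 0-based
      hit <- feats$feature[feats$start <= pos0 & feats$end > pos0]
      if (length(hit)) return(hit[1])
      if (pos0 >= g0 && pos0 < g1) return("intron")
      "flank"
    }, "")
    snp_rows[[length(snp_rows) + 1]] <- data.frame(
      gene = gene, contig = ct, pos = gm$pos[in_range], region = region,
      differentiated = apply(freqs[in_range, , drop = FALSE] >= diff_freq,
                             1, any, na.rm = TRUE),
      large_diff = dif[in_range] >= large_diff_freq,
      freqs[in_range, , drop = FALSE], stringsAsFactors = FALSE)
  }
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(gene = character(), contig = character(), pos = integer(),
               region = character(), differentiated = logical(),
               large_diff = logical())
  genes <- data.frame(
    gene = candidates$gene,
    n_snps = vapply(candidates$gene, function(g) sum(snps$gene == g), 0L),
    n_diff = vapply(candidates$gene, function(g)
      sum(snps$differentiated[snps$gene == g]), 0L),
    coding_diff = vapply(candidates$gene, function(g)
      any(snps$differentiated[snps$gene == g & snps$region == "exon"]), TRUE),
    stringsAsFactors = FALSE)
  list(snps = snps, genes = genes)
}
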