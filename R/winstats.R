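## Sliding-window differentiation statistics: nucleotide diversity (pi),
## Weir-Cockerham weighted FST and absolute divergence dXY, plus genotype
## PCA.  Window denominators use the full window length (invariant sites
## contribute 0), i.e. per-site statistics over fixed windows.

#' Build a sliding-window grid over contigs
#'
#' Full windows of `window` bp advanced by `step` bp start at 0; if the
#' contig end is not covered by the last full window, one truncated trailing
#' window is added (and flagged), so every bp is covered.  Contigs shorter
#' than `window` get a single truncated window.
#'
#' @param contig_lengths named vector of contig lengths (bp).
#' @param window,step window length and increment in bp (defaults 10 kb /
#'   2 kb).
#' @return data.frame(contig, start, end, full); 0-based half-open.
#' @export
make_windows <- function(contig_lengths, window = 10000, step = 2000) {
  stopifnot(all(contig_lengths > 0), window > 0, step > 0)
  out <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    if (len < window)
      return(data.frame(contig = ct, start = 0, end = len, full = FALSE))
    starts <- seq(0, len - window, by = step)
    df <- data.frame(contig = ct, start = starts, end = starts + window,
                     full = TRUE)
    covered <- starts[length(starts)] + window
    if (covered < len)
      df <- rbind(df, data.frame(contig = ct,
                                 start = starts[length(starts)] + step,
                                 end = len, full = FALSE))
    df
  })
  do.call(rbind, out)
}

## Map variant rows of gm onto (overlapping) windows; returns a two-column
## matrix (site row, window row).
.site_window_map <- function(gm, windows) {
  lv <- union(unique(gm$contig), unique(windows$contig))
  sgr <- GenomicRanges::GRanges(factor(gm$contig, lv),
                                IRanges::IRanges(gm$pos, gm$pos))
  wgr <- GenomicRanges::GRanges(factor(windows$contig, lv),
                                IRanges::IRanges(windows$start + 1,
                                                 windows$end))
  ov <- GenomicRanges::findOverlaps(sgr, wgr)
  cbind(site = S4Vectors::queryHits(ov), win = S4Vectors::subjectHits(ov))
}

## Sum per-site values over windows. vals may be a matrix (columns summed
## independently); returns matrix n_windows x ncol.
.window_sum <- function(map, vals, n_win) {
  vals <- as.matrix(vals)
  out <- matrix(0, n_win, ncol(vals))
  for (k in seq_len(ncol(vals))) {
    v <- vals[map[, "site"], k]
    ok <- !is.na(v)
    s <- rowsum(v[ok], map[ok, "win"])
    out[as.integer(rownames(s)), k] <- s
  }
  out
}

#' Window nucleotide diversity for one species
#'
#' Site pi = 2 c_ref c_alt / (m (m - 1)) over called alleles of the species;
#' window pi = sum of site terms / window length.  Windows overlapping
#' variant rows at which fewer than two alleles are called anywhere are NA.
#'
#' @param gm a [genotype_matrix].
#' @param windows window grid from [make_windows()].
#' @param species species name.
#' @return numeric vector of per-window pi.
#' @export
window_pi <- function(gm, windows, species) {
  cols <- gm$samples[gm$species == species]
  if (!length(cols)) stop("unknown species: ", species)
  d <- gm$dos[, cols, drop = FALSE]
  m <- 2 * rowSums(!is.na(d))
  calt <- rowSums(d, na.rm = TRUE)
  site <- ifelse(m >= 2, 2 * calt * (m - calt) / (m * (m - 1)), NA_real_)
  map <- .site_window_map(gm, windows)
  L <- windows$end - windows$start
  tot <- .window_sum(map, site, nrow(windows))[, 1]
  pi <- tot / L
  ## windows whose only variant rows are uncallable -> missing
  has_row <- .window_sum(map, rep(1, length(site)), nrow(windows))[, 1] > 0
  usable <- .window_sum(map, as.numeric(!is.na(site)), nrow(windows))[, 1] > 0
  pi[has_row & !usable] <- NA_real_
  pi
}

## Per-site Weir & Cockerham (1984) variance components for two populations.
## Returns data.frame(a, b, c); rows where the components are undefined (a
## population with no called genotypes, or nbar <= 1) are NA.
.wc_components <- function(gm, speciesA, speciesB) {
  ca <- gm$samples[gm$species == speciesA]
  cb <- gm$samples[gm$species == speciesB]
  if (!length(ca) || !length(cb)) stop("unknown species pair")
  da <- gm$dos[, ca, drop = FALSE]
  db <- gm$dos[, cb, drop = FALSE]
  n1 <- rowSums(!is.na(da))
  n2 <- rowSums(!is.na(db))
  p1 <- rowSums(da, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(db, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(da == 1, na.rm = TRUE) / n1
  h2 <- rowSums(db == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1 & nc > 0
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_
  b[!ok] <- NA_real_
  cc[!ok] <- NA_real_
  data.frame(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham weighted FST for a species pair
#'
#' Ratio of sums: window FST = sum(a) / sum(a + b + c) over sites in the
#' window; sites with a + b + c = 0 (both species monomorphic for the same
#' allele) are skipped; windows with no usable site are NA.  The genome-wide
#' weighted mean is the same ratio over all sites.
#'
#' @inheritParams window_pi
#' @param speciesA,speciesB the species pair.
#' @return list with `fst` (per-window), `genome_fst` (scalar) and `n_used`
#'   (usable sites per window).
#' @export
window_weighted_fst <- function(gm, windows, speciesA, speciesB) {
  w <- .wc_components(gm, speciesA, speciesB)
  denom_site <- w$a + w$b + w$c
  use <- !is.na(denom_site) & denom_site != 0
  a_use <- ifelse(use, w$a, NA_real_)
  d_use <- ifelse(use, denom_site, NA_real_)
  map <- .site_window_map(gm, windows)
  nums <- .window_sum(map, cbind(a_use, d_use, as.numeric(use)),
                      nrow(windows))
  fst <- ifelse(nums[, 3] > 0, nums[, 1] / nums[, 2], NA_real_)
  list(fst = fst,
       genome_fst = sum(w$a[use]) / sum(denom_site[use]),
       n_used = nums[, 3])
}

#' Windowed absolute divergence dXY for a species pair
#'
#' Site term p_A (1 - p_B) + p_B (1 - p_A); window dXY = sum of site terms /
#' window length (invariant sites contribute 0).  Symmetric in A and B.
#'
#' @inheritParams window_weighted_fst
#' @return numeric vector of per-window dXY.
#' @export
window_dxy <- function(gm, windows, speciesA, speciesB) {
  pa <- allele_freq(gm, speciesA)[, 1]
  pb <- allele_freq(gm, speciesB)[, 1]
  site <- pa * (1 - pb) + pb * (1 - pa)
  map <- .site_window_map(gm, windows)
  L <- windows$end - windows$start
  tot <- .window_sum(map, site, nrow(windows))[, 1]
  dxy <- tot / L
  has_row <- .window_sum(map, rep(1, length(site)), nrow(windows))[, 1] > 0
  usable <- .window_sum(map, as.numeric(!is.na(site)), nrow(windows))[, 1] > 0
  dxy[has_row & !usable] <- NA_real_
  dxy
}

#' Full window-statistic table for a set of species
#'
#' Computes per-window pi for every species and weighted FST / dXY for every
#' species pair on one grid.
#'
#' @param gm a [genotype_matrix].
#' @param contig_lengths named contig lengths (bp); defaults to the maximum
#'   observed position per contig.
#' @param species species included (default: all in the matrix).
#' @param window,step grid parameters (defaults 10 kb / 2 kb).
#' @return object of class `window_stats`: the window data.frame with stat
#'   columns `pi_<sp>`, `fst_<A>_<B>`, `dxy_<A>_<B>`, `n_var`, and an
#'   attribute `genome_fst` (named per pair).
#' @export
window_stats <- function(gm, contig_lengths = NULL,
                         species = unique(gm$species), window = 10000,
                         step = 2000) {
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(gm$pos, gm$contig, max)
    contig_lengths <- setNames(as.numeric(contig_lengths),
                               names(contig_lengths))
  }
  win <- make_windows(contig_lengths, window = window, step = step)
  map <- .site_window_map(gm, win)
  win$n_var <- .window_sum(map, rep(1, n_sites(gm)), nrow(win))[, 1]
  for (sp in species) win[[paste0("pi_", sp)]] <- window_pi(gm, win, sp)
  genome_fst <- c()
  if (length(species) > 1) {
    pairs <- combn(species, 2)
    for (k in seq_len(ncol(pairs))) {
      A <- pairs[1, k]; B <- pairs[2, k]
      f <- window_weighted_fst(gm, win, A, B)
      win[[paste0("fst_", A, "_", B)]] <- f$fst
      win[[paste0("dxy_", A, "_", B)]] <- window_dxy(gm, win, A, B)
      genome_fst[paste(A, B, sep = "_")] <- f$genome_fst
    }
  }
  attr(win, "genome_fst") <- genome_fst
  class(win) <- c("window_stats", "data.frame")
  win
}

#' Genotype PCA (smartpca-style scaling)
#'
#' Dosages are centred by 2p and scaled by sqrt(2p(1-p)) with p the pooled
#' allele frequency; coordinates are the eigenvectors of the individual x
#' individual covariance matrix, scaled by the square roots of their
#' eigenvalues.  Missing dosages are mean-imputed.  Deterministic up to the
#' sign of each axis.
#'
#' @param gm a [genotype_matrix], typically after MAF filtering and LD
#'   pruning.
#' @param k number of components to return.
#' @return list with `coords` (individuals x k), `eigenvalues` and
#'   `explained` (fraction of variance per axis).
#' @export
pca_genotypes <- function(gm, k = 10) {
  if (length(gm$samples) < 2) stop("need >= 2 individuals")
  X <- gm$dos
  p <- rowMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  k <- min(k, length(gm$samples))
  if (!any(poly)) {
    z <- matrix(0, length(gm$samples), k,
                dimnames = list(gm$samples, paste0("PC", seq_len(k))))
    return(list(coords = z, eigenvalues = rep(0, k), explained = rep(0, k)))
  }
  X <- X[poly, , drop = FALSE]
  p <- p[poly]
  X[is.na(X)] <- (2 * p)[which(is.na(X), arr.ind = TRUE)[, 1]]
  Z <- (X - 2 * p) / sqrt(2 * p * (1 - p))
  G <- crossprod(Z) / nrow(Z)
  e <- eigen(G, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  dimnames(coords) <- list(gm$samples, paste0("PC", seq_len(k)))
  list(coords = coords, eigenvalues = ev[seq_len(k)],
       explained = ev[seq_len(k)] / sum(ev))
}
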