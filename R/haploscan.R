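## EHH / iHH / iHS selection scan on phased haplotypes.
##
## Conventions: EHH for an allele class is the probability that two randomly
## drawn carrier haplotypes are identical over the interval from the core to
## the query site.  iHH integrates EHH against physical position
## (trapezoids), separately for the ancestral (A) and derived (D) classes,
## truncating where EHH drops below `cutoff` or across inter-SNP gaps larger
## than `max_gap`.  Unstandardised iHS = ln(iHH_A / iHH_D), so positive
## scores mean unusually long ancestral-allele haplotypes and negative
## scores long derived-allele haplotypes; scores are standardised within
## derived-allele-frequency bins.

## EHH decay to one side of the core for one carrier set.
## sites: site indices ordered outward from the core; returns matrix
## (distance, ehh), truncated at the first point below cutoff (included).
.ehh_side <- function(hap, positions, carriers, core, sites, cutoff,
                      max_gap) {
  n <- length(carriers)
  denom <- choose(n, 2)
  grp <- rep(1L, n)
  dist <- numeric(0)
  ehh <- numeric(0)
  prev_pos <- positions[core]
  decayed <- FALSE
  for (s in sites) {
    if (abs(positions[s] - prev_pos) > max_gap) break
    prev_pos <- positions[s]
    a <- hap[s, carriers]
    key <- grp * 2L + a
    grp <- match(key, unique(key))
    e <- sum(choose(tabulate(grp), 2)) / denom
    dist <- c(dist, abs(positions[s] - positions[core]))
    ehh <- c(ehh, e)
    if (e < cutoff) {
      decayed <- TRUE
      break
    }
  }
  out <- cbind(distance = dist, ehh = ehh)
  attr(out, "decayed") <- decayed
  out
}

## Trapezoidal integral of an EHH profile starting at (0, 1).
.ihh_integral <- function(prof) {
  x <- c(0, prof[, "distance"])
  y <- c(1, prof[, "ehh"])
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' EHH profile and integrated haplotype homozygosity at one core SNP
#'
#' @param hap sites x haplotypes 0/1 matrix (phased).
#' @param positions site positions (bp), sorted.
#' @param core site index of the core SNP.
#' @param anc allele (0 or 1) that is ancestral at the core.
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param max_gap maximum inter-SNP gap integrated across (default 20 kb).
#' @return list with per-class EHH profiles (`ehh_anc`, `ehh_der`; each a
#'   two-sided list of distance/ehh matrices) and `ihh_a`, `ihh_d`.
#' @export
compute_ehh_ihh <- function(hap, positions, core, anc = 0, cutoff = 0.05,
                            max_gap = 20000) {
  a <- hap[core, ]
  carriers_a <- which(a == anc)
  carriers_d <- which(a == 1 - anc)
  if (length(carriers_a) < 2 || length(carriers_d) < 2)
    stop("core allele class with fewer than 2 haplotypes")
  left <- rev(seq_len(core - 1))
  right <- seq(core + 1, length.out = max(0, length(positions) - core))
  prof <- function(car) {
    list(left = .ehh_side(hap, positions, car, core, left, cutoff, max_gap),
         right = .ehh_side(hap, positions, car, core, right, cutoff,
                           max_gap))
  }
  pa <- prof(carriers_a)
  pd <- prof(carriers_d)
  list(ehh_anc = pa, ehh_der = pd,
       ihh_a = .ihh_integral(pa$left) + .ihh_integral(pa$right),
       ihh_d = .ihh_integral(pd$left) + .ihh_integral(pd$right),
       decayed = all(vapply(c(pa, pd), function(p)
         isTRUE(attr(p, "decayed")), TRUE)))
}

#' Standardise iHS scores within derived-allele-frequency bins
#'
#' Scores are centred and scaled within `n_bins` equal-width frequency bins;
#' bins with fewer than two scores (or zero variance) yield missing
#' standardised values.  The extreme flag marks the top `crit` fraction of
#' absolute standardised scores (two-sided; ties at the threshold included).
#'
#' @param tbl data.frame with columns `daf` (derived allele frequency) and
#'   `ihs_raw`.
#' @param n_bins number of frequency bins (default 50).
#' @param crit total flagged mass (default 0.01).
#' @return `tbl` with `ihs_std` and `extreme` columns; attribute
#'   `extreme_threshold`.
#' @export
ihs_scores <- function(tbl, n_bins = 50, crit = 0.01) {
  std <- rep(NA_real_, nrow(tbl))
  if (nrow(tbl)) {
    bin <- cut(tbl$daf, breaks = seq(0, 1, length.out = n_bins + 1),
               include.lowest = TRUE)
    for (b in levels(bin)) {
      i <- which(bin == b & !is.na(tbl$ihs_raw))
      if (length(i) < 2) next
      mu <- mean(tbl$ihs_raw[i])
      s <- sqrt(mean((tbl$ihs_raw[i] - mu)^2))  # population moments
      if (s == 0) {
        warning("iHS bin ", b, " has zero variance; scores set missing")
        next
      }
      std[i] <- (tbl$ihs_raw[i] - mu) / s
    }
  }
  tbl$ihs_std <- std
  ok <- !is.na(std)
  tbl$extreme <- FALSE
  thr <- NA_real_
  if (any(ok)) {
    k <- max(1, ceiling(crit * sum(ok) - 1e-9))
    thr <- sort(abs(std[ok]), decreasing = TRUE)[k]
    tbl$extreme[ok] <- abs(std[ok]) >= thr
  }
  attr(tbl, "extreme_threshold") <- thr
  tbl
}

#' iHS scan over all usable cores for one species
#'
#' Requires phased input.  Cores with minor allele frequency below
#' `maf_floor`, or an allele class with fewer than two haplotypes, or a zero
#' iHH on either side are skipped.  Ancestral alleles come from the
#' reference allele (`anc = "ref"`, appropriate when the reference carries
#' ancestral states, as in the simulator output), from the major allele of
#' an outgroup species (`anc_species`), or from a caller-supplied 0/1 vector
#' per site.
#'
#' @param gm a phased [genotype_matrix].
#' @param species species scanned.
#' @param anc `"ref"` or an integer vector (0/1 per site: the ancestral
#'   allele code).
#' @param anc_species optional species whose major allele defines the
#'   ancestral state (overrides `anc`).
#' @param maf_floor minimum within-species minor allele frequency at cores.
#' @param cutoff,max_gap see [compute_ehh_ihh()].
#' @param n_bins,crit see [ihs_scores()].
#' @return an iHS table: contig, pos, daf, ihh_a, ihh_d, ihs_raw, ihs_std,
#'   extreme.
#' @export
scan_species <- function(gm, species, anc = "ref", anc_species = NULL,
                         maf_floor = 0.05, cutoff = 0.05, max_gap = 20000,
                         n_bins = 50, crit = 0.01) {
  if (!gm$phased)
    stop("iHS requires phased input (no haplotype matrix present)")
  cols <- which(gm$hap_sample %in% gm$samples[gm$species == species])
  if (!length(cols)) stop("unknown species: ", species)
  anc_vec <- if (!is.null(anc_species)) {
    as.integer(allele_freq(gm, anc_species)[, 1] > 0.5)  # major = ancestral
  } else if (identical(anc, "ref")) {
    rep(0L, n_sites(gm))
  } else {
    stopifnot(length(anc) == n_sites(gm))
    as.integer(anc)
  }
  rows <- list()
  for (ct in unique(gm$contig)) {
    sites <- which(gm$contig == ct)
    hap <- gm$hap[sites, cols, drop = FALSE]
    positions <- gm$pos[sites]
    freq1 <- rowMeans(hap)
    anc_ct <- anc_vec[sites]
    daf <- ifelse(anc_ct == 0, freq1, 1 - freq1)
    maf <- pmin(freq1, 1 - freq1)
    usable <- which(maf >= maf_floor & freq1 * ncol(hap) >= 2 &
                      (1 - freq1) * ncol(hap) >= 2)
    if (!length(usable)) next
    res <- ehh_scan_cpp(hap, as.numeric(positions), usable, anc_ct[usable],
                        cutoff, max_gap)
    ## skip cores whose EHH hits the region end or a gap before decaying
    ## below the cutoff (their integrals are truncated and biased), and
    ## cores with a zero-length side integral
    keep <- res$decayed & res$ihh_a > 0 & res$ihh_d > 0
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      contig = ct, pos = positions[usable[keep]], daf = daf[usable[keep]],
      ihh_a = res$ihh_a[keep], ihh_d = res$ihh_d[keep],
      ihs_raw = log(res$ihh_a[keep] / res$ihh_d[keep]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(contig = character(), pos = integer(), daf = numeric(),
                      ihh_a = numeric(), ihh_d = numeric(),
                      ihs_raw = numeric(), ihs_std = numeric(),
                      extreme = logical()))
  ihs_scores(do.call(rbind, rows), n_bins = n_bins, crit = crit)
}
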