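# Independent scalar/brute-force reference implementations used as oracles.
# These deliberately avoid the package's vectorised code paths.

# --- per-site statistics ----------------------------------------------------

# site pi by enumeration of all allele pairs
pi_site_oracle <- function(alleles) {
  m <- length(alleles)
  if (m < 2) return(NA_real_)
  s <- 0
  for (i in 1:(m - 1))
    for (j in (i + 1):m) s <- s + (alleles[i] != alleles[j])
  s / choose(m, 2)
}

# site dxy by enumeration of all between-group allele pairs
dxy_site_oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) s <- s + (a[i] != b[j])
  s / (length(a) * length(b))
}

# literal transcription of the Weir & Cockerham (1984) two-population
# variance components (r = 2)
wc_site_oracle <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# window FST/dxy/pi recomputed site by site from a genotype matrix
window_fst_oracle <- function(gm, win, spA, spB) {
  ca <- gm$samples[gm$species == spA]
  cb <- gm$samples[gm$species == spB]
  num <- den <- 0
  used <- FALSE
  for (s in which(gm$contig == win$contig & gm$pos > win$start &
                    gm$pos <= win$end)) {
    da <- gm$dos[s, ca]; db <- gm$dos[s, cb]
    da <- da[!is.na(da)]; db <- db[!is.na(db)]
    if (!length(da) || !length(db)) next
    w <- wc_site_oracle(length(da), length(db), mean(da) / 2, mean(db) / 2,
                        mean(da == 1), mean(db == 1))
    if (sum(w) == 0 || is.na(sum(w))) next
    num <- num + w["a"]; den <- den + sum(w); used <- TRUE
  }
  if (!used) NA_real_ else unname(num / den)
}

# --- HWE exact distribution by downward/upward recurrence -------------------
# (independent route: Wigginton-style recurrence instead of the closed-form
# log-factorial expression used by the implementation)
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nr <- 2 * min(nAA, naa) + nAa
  if (nr == 0) return(1)
  hets <- seq(nr %% 2, nr, by = 2)
  p <- setNames(numeric(length(hets)), hets)
  mid <- hets[which.min(abs(hets - nr * (2 * n - nr) / (2 * n)))]
  p[as.character(mid)] <- 1
  h <- mid
  while (h - 2 >= hets[1]) {          # going down in het count
    hom_min <- (nr - h) / 2
    hom_maj <- n - h - hom_min
    p[as.character(h - 2)] <- p[as.character(h)] * h * (h - 1) /
      (4 * (hom_min + 1) * (hom_maj + 1))
    h <- h - 2
  }
  h <- mid
  while (h + 2 <= nr) {               # going up
    hom_min <- (nr - h) / 2
    hom_maj <- n - h - hom_min
    p[as.character(h + 2)] <- p[as.character(h)] *
      4 * hom_min * hom_maj / ((h + 2) * (h + 1))
    h <- h + 2
  }
  p <- p / sum(p)
  obs <- p[as.character(nAa)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# --- brute-force greedy LD pruning oracle -----------------------------------
ld_prune_oracle <- function(dos, maf, window_snps = 50, step_snps = 5,
                            r2_max = 0.1) {
  p <- ncol(dos)  # here dos is individuals x snps
  keep <- rep(TRUE, p)
  s <- 1
  repeat {
    win <- s:min(s + window_snps - 1, p)
    for (i in win) {
      if (!keep[i]) next
      for (j in win) {
        if (j <= i || !keep[j] || !keep[i]) next
        r2 <- suppressWarnings(stats::cor(dos[, i], dos[, j]))^2
        if (is.na(r2)) r2 <- 0
        if (r2 > r2_max) {
          if (maf[j] < maf[i] || maf[j] == maf[i]) keep[j] <- FALSE
          else { keep[i] <- FALSE; break }
        }
      }
    }
    if (s + window_snps - 1 >= p) break
    s <- s + step_snps
  }
  which(keep)
}

# --- Mann-Whitney by explicit enumeration -----------------------------------
mw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  dev <- abs(U_obs - n * m / 2)
  sets <- utils::combn(n + m, n)
  Us <- apply(sets, 2, function(ix) sum(r[ix])) - n * (n + 1) / 2
  mean(abs(Us - n * m / 2) >= dev - 1e-12)
}

# --- four-point condition oracle for 4-taxon additive matrices --------------
# returns the index (1..3) of the true split: 12|34, 13|24, 14|23
four_point_oracle <- function(D) {
  sums <- c(D[1, 2] + D[3, 4], D[1, 3] + D[2, 4], D[1, 4] + D[2, 3])
  which.min(sums)
}

# random additive distance matrix on 4 taxa with split 12|34
random_additive_matrix <- function() {
  tips <- runif(4, 0.5, 3)
  x <- runif(1, 0.3, 2)  # internal branch
  D <- matrix(0, 4, 4)
  D[1, 2] <- tips[1] + tips[2]
  D[3, 4] <- tips[3] + tips[4]
  for (i in 1:2) for (j in 3:4) D[i, j] <- tips[i] + x + tips[j]
  D <- D + t(D)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  D
}
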