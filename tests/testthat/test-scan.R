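# HDR calling, specificity, sweep flags, gene mapping, SNP annotation.

# window table with a single stat column for one pair
fake_stats <- function(fst, dxy = NULL, contig = "c1", step = 2000,
                       window = 10000) {
  n <- length(fst)
  df <- data.frame(contig = contig, start = (seq_len(n) - 1) * step,
                   end = (seq_len(n) - 1) * step + window, full = TRUE,
                   n_var = 10L)
  df$fst_A_B <- fst
  df$dxy_A_B <- if (is.null(dxy)) fst else dxy
  class(df) <- c("window_stats", "data.frame")
  df
}

test_that("call_hdrs selects exactly the top 0.5% and merges overlaps", {
  set.seed(6)
  st <- fake_stats(sample(seq(0.001, 1, length.out = 1000)))
  h <- call_hdrs(st, "A_B")
  # 0.5% of 1,000 distinct values -> exactly 5 outlier windows
  expect_length(attr(h, "outlier_windows"), 5)
  expect_equal(sum(h$n_windows), 5)
  # merge rule: overlapping outlier windows become one region
  st2 <- fake_stats(c(0.9, 0.95, rep(0.1, 398)))
  h2 <- suppressWarnings(call_hdrs(st2, "A_B"))
  expect_equal(nrow(h2), 1)
  expect_equal(c(h2$start, h2$end), c(0, 12000))
  expect_error(call_hdrs(fake_stats(rep(NA_real_, 300)), "A_B"),
               "all-missing")
  expect_warning(call_hdrs(fake_stats(runif(150)), "A_B"), "unstable")
})

test_that("call_hdrs equals a brute-force threshold-and-merge oracle", {
  set.seed(16)
  for (rep in 1:5) {
    v <- round(runif(600), 3)  # ties likely
    st <- fake_stats(v)
    h <- call_hdrs(st, "A_B")
    k <- ceiling(0.005 * 600)
    thr <- sort(v, decreasing = TRUE)[k]
    out <- which(v >= thr)
    # brute-force merge of book-ended/overlapping windows
    regions <- list()
    cur <- c(st$start[out[1]], st$end[out[1]])
    for (i in out[-1]) {
      if (st$start[i] <= cur[2]) cur[2] <- st$end[i]
      else { regions[[length(regions) + 1]] <- cur; cur <- c(st$start[i], st$end[i]) }
    }
    regions[[length(regions) + 1]] <- cur
    mat <- do.call(rbind, regions)
    expect_equal(h$start, mat[, 1])
    expect_equal(h$end, mat[, 2])
    expect_equal(attr(h, "threshold"), thr)
  }
})

test_that("windows tied at the threshold are all included", {
  st <- fake_stats(c(rep(0.99, 4), seq(0.1, 0.9, length.out = 396)))
  h <- suppressWarnings(call_hdrs(st, "A_B"))
  # k = 2 but 4 windows tie at the threshold value
  expect_length(attr(h, "outlier_windows"), 4)
})

test_that("sweep_flag requires joint FST and dXY outliers", {
  fst <- c(rep(0.2, 496), 0.95, 0.96, 0.97, 0.98)
  dxy <- c(rep(0.001, 496), 0.05, 0.0011, 0.05, 0.0012)
  st <- fake_stats(fst, dxy)
  h <- call_hdrs(st, "A_B")
  h <- sweep_flag(st, h, "A_B")
  # windows 497..500 merge into regions; those containing a top-dXY window
  # are flagged, high-FST/median-dXY ones are not
  expect_true(any(h$sweep))
  # high FST but median dXY: top dXY windows lie outside every HDR
  dxy2 <- rep(0.001, 500)
  dxy2[c(10, 20, 30)] <- 0.05
  st2 <- fake_stats(fst, dxy2)
  h2 <- call_hdrs(st2, "A_B")
  h2 <- sweep_flag(st2, h2, "A_B")
  expect_false(any(h2$sweep))
})

test_that("specificity labels follow the two-pair intersection rule", {
  mk <- function(contig, start, end)
    data.frame(contig = contig, start = start, end = end,
               pair = NA, stringsAsFactors = FALSE)
  hdrs <- list(
    "HChi_HSau" = mk("c1", 10000, 20000),
    "HChi_LRuf" = mk("c1", 14000, 22000),
    "HSau_LRuf" = mk("c2", 0, 5000))
  lab <- assign_specificity(hdrs)
  expect_equal(lab[["HChi_HSau"]]$label, "HChi_specific")
  expect_equal(lab[["HChi_LRuf"]]$label, "HChi_specific")
  expect_equal(lab[["HSau_LRuf"]]$label, "pair_only")
  # same interval in all three pairs -> multi_pair
  hdrs3 <- list("A_B" = mk("c1", 0, 1000), "A_C" = mk("c1", 0, 1000),
                "B_C" = mk("c1", 500, 900))
  lab3 <- assign_specificity(hdrs3)
  expect_true(all(vapply(lab3, function(x) x$label, "") == "multi_pair"))
})

test_that("gene mapping honours the 10-kb flank and matches the overlap oracle", {
  hdrs <- data.frame(contig = "c1", start = 100000, end = 110000,
                     pair = "A_B", stringsAsFactors = FALSE)
  genes <- data.frame(
    gene = c("near", "far"), contig = "c1",
    start = c(115000, 125000), end = c(118000, 128000),
    feature = "gene", stringsAsFactors = FALSE)
  cand <- map_genes_to_hdrs(hdrs, genes)
  expect_equal(cand$gene, "near")   # 5 kb gap in, 15 kb gap out
  expect_warning(
    map_genes_to_hdrs(hdrs, data.frame(gene = "g", contig = "cX", start = 1,
                                       end = 10, feature = "gene"),
                      contigs = "c1"), "unknown contig")
  # randomized sets vs brute-force O(n*m) overlap
  set.seed(19)
  for (rep in 1:3) {
    hs <- data.frame(contig = sample(c("c1", "c2"), 15, TRUE),
                     start = sample.int(2e5, 15), stringsAsFactors = FALSE)
    hs$end <- hs$start + sample.int(30000, 15)
    hs$pair <- "A_B"
    gs <- data.frame(gene = paste0("g", 1:25),
                     contig = sample(c("c1", "c2"), 25, TRUE),
                     start = sample.int(2e5, 25), stringsAsFactors = FALSE)
    gs$end <- gs$start + sample.int(20000, 25)
    gs$feature <- "gene"
    got <- sort(map_genes_to_hdrs(hs, gs)$gene)
    want <- sort(gs$gene[vapply(seq_len(25), function(i)
      any(hs$contig == gs$contig[i] & hs$start < gs$end[i] + 10000 &
            hs$end > gs$start[i] - 10000), TRUE)])
    expect_equal(got, want)
  }
})

test_that("candidate genes always overlap their flank-expanded HDR", {
  set.seed(23)
  hs <- data.frame(contig = "c1", start = sample.int(1e5, 10))
  hs$end <- hs$start + 5000
  hs$pair <- "A_B"
  gs <- data.frame(gene = paste0("g", 1:40), contig = "c1",
                   start = sample.int(1.5e5, 40), feature = "gene")
  gs$end <- gs$start + 3000
  cand <- map_genes_to_hdrs(hs, gs)
  for (i in seq_len(nrow(cand)))
    expect_true(any(hs$start < cand$end[i] + 10000 &
                      hs$end > cand$start[i] - 10000))
})

test_that("SNP annotation assigns genic regions and differentiation flags", {
  spAB <- setNames(rep(c("A", "B"), each = 5), paste0("i", 1:10))
  # sites: exon (diff), intron (large diff), flank (no flags)
  dos <- rbind(c(rep(2L, 4), 1L, rep(0L, 5)),     # pA=0.9, pB=0   exon
               c(rep(2L, 4), 1L, 1L, rep(0L, 4)), # pA=0.9, pB=0.1 intron
               c(rep(1L, 2), rep(0L, 8)))         # freq 0.2/0     flank
  gm <- toy_gm(dos, spAB, pos = c(1500L, 4000L, 9000L))
  models <- data.frame(gene = "g1", contig = "chr1",
                       start = c(1000, 1000, 5000),
                       end = c(6000, 2000, 6000),
                       feature = c("gene", "exon", "exon"))
  cand <- data.frame(gene = "g1", contig = "chr1", start = 1000, end = 6000,
                     pairs = "A_B", max_dxy = NA)
  ann <- annotate_differentiated_snps(gm, cand, models, pair = c("A", "B"))
  expect_equal(ann$snps$region, c("exon", "intron", "flank"))
  expect_equal(ann$snps$differentiated, c(TRUE, TRUE, FALSE))
  expect_equal(ann$snps$large_diff, c(TRUE, TRUE, FALSE))
  expect_true(ann$genes$coding_diff[1])
})
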