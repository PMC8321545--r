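test_that("read_vcf parses genotypes, flags indels/multiallelics, keeps phase", {
  path <- write_mini_vcf(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t200\t.\tA\tAT\t.\tPASS\t.\tGT\t0|0\t0|1",
    "chr1\t300\t.\tC\tT\t.\tPASS\t.\tGT\t.|.\t0|1"),
    samples = c("s1", "s2"))
  gm <- read_vcf(path, c(s1 = "spA", s2 = "spB"))
  expect_equal(dim(gm$dos), c(3L, 2L))
  expect_equal(gm$dos[1, ], c(s1 = 1L, s2 = 2L))
  expect_true(gm$indel[2])
  expect_false(gm$indel[1])
  expect_true(is.na(gm$dos[3, "s1"]))
  expect_true(gm$phased)
  expect_equal(gm$hap[1, ], c(0L, 1L, 1L, 1L))
})

test_that("read_vcf errors name the unmapped sample", {
  path <- write_mini_vcf("chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
                         samples = c("s1", "s2"))
  expect_error(read_vcf(path, c(s1 = "spA")), "s2")
})

test_that("write_vcf / read_vcf round-trips a phased matrix", {
  species <- setNames(rep(c("X", "Y"), each = 2), paste0("i", 1:4))
  set.seed(1)
  hap <- matrix(rbinom(40 * 8, 1, 0.4), 40, 8)
  gm <- toy_gm_phased(hap, species)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path, species)
  expect_identical(gm2$dos, gm$dos)
  expect_identical(unname(gm2$hap), unname(gm$hap))
  expect_equal(gm2$pos, gm$pos)
})

test_that("hwe_exact_test matches hand-derived examples and conventions", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 2, 0), 1, tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 0, 0), 1)   # monomorphic convention
  # symmetry in hom classes
  expect_equal(hwe_exact_test(7, 3, 2), hwe_exact_test(2, 3, 7))
  # agreement with the recurrence oracle on assorted configurations
  for (cfg in list(c(10, 0, 10), c(3, 4, 5), c(0, 6, 1), c(8, 1, 1))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-12)
  }
})

test_that("filter_sites applies the rule chain and logs each drop", {
  species <- setNames(rep("sp", 20), paste0("i", 1:20))
  dos <- matrix(0L, 6, 20)
  dos[1, 1:5] <- 1L                      # clean polymorphic site
  dos[2, ] <- rep(c(0L, 2L), 10)         # AA=10, aa=10: HWE p = 2.9e-4
  dos[3, 1] <- NA                        # one missing call
  dos[4, 1:8] <- 1L                      # clean
  dos[5, 3] <- 1L                        # will be flagged indel below
  dos[6, 4] <- 1L                        # will be flagged multiallelic below
  gm <- toy_gm(dos, species)
  gm$indel[5] <- TRUE
  gm$multiallelic[6] <- TRUE
  expect_lt(hwe_exact_test(10, 0, 10), 0.001)  # the designed HWE failure
  res <- filter_sites(gm, filter_config())
  expect_equal(n_sites(res$genotypes), 2)
  expect_equal(res$genotypes$pos, gm$pos[c(1, 4)])
  expect_setequal(res$log$rule, c("hwe", "missing", "indel", "multiallelic"))
  # all-clean input is untouched; disabled filters are the identity
  clean <- gm_subset(gm, c(1, 4))
  expect_equal(n_sites(filter_sites(clean)$genotypes), 2)
  off <- filter_config(require_biallelic = FALSE, max_missing_fraction = 1,
                       drop_indels = FALSE, hwe_alpha = NA)
  expect_equal(n_sites(filter_sites(gm, off)$genotypes), 6)
})

test_that("filter_sites is idempotent", {
  set.seed(3)
  species <- setNames(rep(c("A", "B"), each = 6), paste0("i", 1:12))
  dos <- matrix(rbinom(50 * 12, 2, 0.3), 50, 12)
  gm <- toy_gm(dos, species)
  once <- filter_sites(gm)$genotypes
  twice <- filter_sites(once)$genotypes
  expect_identical(twice$pos, once$pos)
  expect_identical(twice$dos, once$dos)
})

test_that("ld_prune removes duplicated columns and keeps independent ones", {
  set.seed(5)
  species <- setNames(rep("sp", 30), paste0("i", 1:30))
  base <- matrix(rbinom(20 * 30, 2, 0.5), 20, 30)
  dup <- rbind(base[1, , drop = FALSE], base)  # site 2 duplicates site 1
  gm <- toy_gm(dup, species)
  kept <- ld_prune(gm)
  expect_false(all(c(1, 2) %in% kept))
  expect_true(any(c(1, 2) %in% kept))
  # independent sites: identity
  gm2 <- toy_gm(base, species)
  r2 <- suppressWarnings(cor(t(base)))^2
  if (max(r2[upper.tri(r2)]) < 0.1)
    expect_equal(ld_prune(gm2), seq_len(20))
})

test_that("ld_prune equals the brute-force greedy oracle on a crafted panel", {
  set.seed(11)
  n_ind <- 40
  p <- 200
  # correlated blocks: each block descends from one template with noise
  dos <- matrix(0L, p, n_ind)
  i <- 1
  while (i <= p) {
    blk <- min(sample(1:6, 1), p - i + 1)
    template <- rbinom(n_ind, 2, runif(1, 0.2, 0.8))
    for (j in seq_len(blk)) {
      flip <- rbinom(n_ind, 1, 0.1)
      x <- template
      x[flip == 1] <- rbinom(sum(flip), 2, 0.5)
      dos[i + j - 1, ] <- x
    }
    i <- i + blk
  }
  species <- setNames(rep("sp", n_ind), paste0("i", seq_len(n_ind)))
  gm <- toy_gm(dos, species)
  pbar <- rowMeans(dos) / 2
  maf <- pmin(pbar, 1 - pbar)
  expect_equal(ld_prune(gm), ld_prune_oracle(t(dos), maf))
})

test_that("ld_prune is invariant to prepending already-pruned sites", {
  set.seed(21)
  n_ind <- 30
  base <- matrix(rbinom(60 * n_ind, 2, 0.4), 60, n_ind)
  dup_head <- rbind(base[1, , drop = FALSE], base)
  species <- setNames(rep("sp", n_ind), paste0("i", seq_len(n_ind)))
  kept_base <- ld_prune(toy_gm(base, species))
  kept_dup <- ld_prune(toy_gm(dup_head, species))
  # after dropping the duplicated head, the kept set is the same
  expect_equal(setdiff(kept_dup, 1) - 1, setdiff(kept_base, integer(0)))
})

test_that("inbreeding coefficient matches the hand-worked case and conventions", {
  species <- setNames(c("sp", "sp"), c("i1", "i2"))
  gm <- toy_gm(matrix(c(1L, 1L), 1, 2), species)  # both het, pooled p = 0.5
  f <- inbreeding_coefficient(gm)
  expect_equal(unname(f["i1"]), -0.5, tolerance = 1e-12)
  # individual with only uninformative sites -> NA
  gm2 <- toy_gm(matrix(c(0L, 0L), 1, 2), species)
  expect_true(all(is.na(inbreeding_coefficient(gm2))))
  expect_error(inbreeding_coefficient(
    toy_gm(matrix(0L, 1, 1), setNames("sp", "i1"))), "individuals")
})

test_that("inbreeding coefficient is near zero under random mating", {
  set.seed(9)
  n_ind <- 20
  p <- runif(10000, 0.05, 0.95)
  dos <- sapply(seq_len(n_ind), function(i) rbinom(10000, 2, p))
  species <- setNames(rep("sp", n_ind), paste0("i", seq_len(n_ind)))
  f <- inbreeding_coefficient(toy_gm(dos, species))
  expect_lt(max(abs(mean(f))), 0.05)
})
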