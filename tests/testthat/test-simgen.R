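# The simulator's own calibration: determinism, bookkeeping, coalescent
# expectations at desk scale.

test_that("same seed gives byte-identical outputs; configs are validated", {
  dem <- single_population_demography(30, n_gen = 50, sample_n = 5)
  mut <- mutation_config(mu = 1e-5, recomb_rate = 1e-6, region_length = 5e3)
  scens <- replicate(2, selection_scenario("neutral"), simplify = FALSE)
  d1 <- tempfile(); d2 <- tempfile()
  write_outputs(simulate_radiation(dem, mut, scens, seed = 99), d1)
  write_outputs(simulate_radiation(dem, mut, scens, seed = 99), d2)
  for (f in c("simulated.vcf", "truth.tsv", "genes.bed", "species_map.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # different seed differs
  d3 <- tempfile()
  write_outputs(simulate_radiation(dem, mut, scens, seed = 100), d3)
  expect_false(identical(readLines(file.path(d1, "simulated.vcf")),
                         readLines(file.path(d3, "simulated.vcf"))))
  # config errors
  expect_error(simulate_radiation(dem, mut, list(
    selection_scenario("de_novo_sweep", target_lineages = "nope")),
    seed = 1), "unknown lineage")
  expect_error(single_population_demography(10, 50, sample_n = 20),
               "sample_n")
})

test_that("write_outputs bookkeeping: sample columns, contigs, truth rows", {
  lineages <- data.frame(
    name = c("P", "Q", "R"), parent = c(NA, "P", "P"),
    create_gen = c(0L, 10L, 20L), size = c(30, 30, 30),
    sample_n = c(10, 10, 10), stringsAsFactors = FALSE)
  dem <- demography_config(lineages, n_gen = 60)
  mut <- mutation_config(mu = 2e-5, recomb_rate = 0, region_length = 4e3)
  sim <- simulate_radiation(dem, mut,
                            replicate(3, selection_scenario("neutral"),
                                      simplify = FALSE), seed = 17)
  out <- tempfile()
  write_outputs(sim, out)
  vcf <- readLines(file.path(out, "simulated.vcf"))
  header <- strsplit(grep("^#CHROM", vcf, value = TRUE), "\t")[[1]]
  expect_length(header, 9 + 30)          # 30 sample columns
  body_contigs <- unique(sub("\t.*", "", grep("^[^#]", vcf, value = TRUE)))
  expect_length(body_contigs, 3)
  truth <- read.table(file.path(out, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 3)
  # round-trip identity against the in-memory matrices
  gm2 <- read_vcf(file.path(out, "simulated.vcf"),
                  file.path(out, "species_map.tsv"))
  gm1 <- do.call(rbind_genotype_matrix, sim$regions)
  expect_equal(gm2$pos, gm1$pos)
  expect_identical(unname(gm2$dos[, gm1$samples]), unname(gm1$dos))
  expect_identical(unname(gm2$hap), unname(gm1$hap))
  # species tree is valid newick with all lineages
  tr <- ape::read.tree(file.path(out, "species_tree.nwk"))
  expect_setequal(tr$tip.label, c("P", "Q", "R"))
})

test_that("neutral pi matches the coalescent expectation 4*N*mu", {
  # theta = 0.005/site held while N is scaled down to desk size
  N <- 100
  dem <- single_population_demography(N, n_gen = 10 * N, sample_n = 10)
  mut <- mutation_config(mu = 0.005 / (4 * N), recomb_rate = 1e-6,
                         region_length = 2e4)
  sim <- simulate_radiation(dem, mut,
                            replicate(25, selection_scenario("neutral"),
                                      simplify = FALSE), seed = 7)
  win <- data.frame(contig = NA, start = 0, end = 2e4, full = TRUE)
  pis <- vapply(sim$regions, function(gm) {
    win$contig <- gm$contig[1]
    window_pi(gm, win, "pop")
  }, 0)
  expect_lt(abs(mean(pis) - 0.005) / 0.005, 0.2)
})

test_that("heterozygosity decays as (1 - 1/2N)^t without mutation/selection", {
  N <- 50
  t <- 100
  dem <- single_population_demography(N, n_gen = t, sample_n = N)
  mut <- mutation_config(mu = 0, recomb_rate = 0, region_length = 1e3)
  hets <- vapply(1:60, function(r) {
    sim <- simulate_radiation(
      dem, mut,
      list(selection_scenario("neutral", selected_position = 500,
                              init_freq = 0.5)), seed = 1000 + r)
    p <- as.numeric(sub(".*pop=", "", sim$truth$sel_freq))
    2 * p * (1 - p)
  }, 0)
  expected <- 0.5 * (1 - 1 / (2 * N))^t
  se <- sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 3 * se + 0.02)
})

test_that("neutral fixation probability approximates the initial frequency", {
  N <- 25
  dem <- single_population_demography(N, n_gen = 500, sample_n = N)
  mut <- mutation_config(mu = 0, recomb_rate = 0, region_length = 1e3)
  p0 <- 0.1
  fixed <- vapply(1:500, function(r) {
    sim <- simulate_radiation(
      dem, mut,
      list(selection_scenario("neutral", selected_position = 500,
                              init_freq = p0)), seed = 5000 + r)
    as.numeric(sub(".*pop=", "", sim$truth$sel_freq)) == 1
  }, TRUE)
  phat <- mean(fixed)
  # binomial 99% CI around p0 over 500 replicates
  expect_lt(abs(phat - p0), 2.6 * sqrt(p0 * (1 - p0) / 500) + 0.01)
})

test_that("de-novo sweeps conditioned on establishment reach high frequency", {
  N <- 100
  dem <- single_population_demography(N, n_gen = 300, sample_n = 10)
  mut <- mutation_config(mu = 1e-6, recomb_rate = 1e-6, region_length = 1e4)
  freqs <- vapply(1:20, function(r) {
    sim <- simulate_radiation(
      dem, mut,
      list(selection_scenario("de_novo_sweep", s = 0.1, h = 0.5,
                              target_lineages = "pop", introduce_gen = 1)),
      seed = 300 + r)
    as.numeric(sub(".*pop=", "", sim$truth$sel_freq))
  }, 0)
  expect_gte(mean(freqs >= 0.9), 0.9)
})

test_that("sgv regions carry a balanced polymorphism older than every split", {
  dem <- radiation_demography(n_focal = 150, n_deep = 25)
  mut <- mutation_config(mu = 4e-6, recomb_rate = 2e-6, region_length = 2e4)
  sim <- simulate_radiation(dem, mut,
                            list(selection_scenario("sgv_sweep",
                                                    target_lineages = "LRuf")),
                            seed = 77)
  tr <- sim$truth
  expect_equal(tr$mode, "sgv_sweep")
  expect_equal(tr$origin_depth, "pre_radiation")
  expect_lt(tr$origin_gen, tr$first_split_gen)  # predates all splits
  # both allele classes survive to sampling in different focal lineages
  freqs <- as.numeric(sub(".*=", "",
                          strsplit(tr$sel_freq, ";")[[1]]))
  names(freqs) <- sub("=.*", "", strsplit(tr$sel_freq, ";")[[1]])
  expect_gte(freqs["LRuf"], 0.9)              # derived class fixed in target
  expect_lte(freqs["HChi"], 0.1)              # ancestral class in the others
})
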