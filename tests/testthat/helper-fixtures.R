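# Programmatic fixtures: tiny genotype matrices, VCF text, simulations.

# genotype matrix from a dosage matrix (sites x individuals)
toy_gm <- function(dos, species, pos = NULL, contig = "chr1", hap = NULL) {
  n <- nrow(dos)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (length(contig) == 1) contig <- rep(contig, n)
  samples <- names(species)
  colnames(dos) <- samples
  genotype_matrix(contig = contig, pos = pos,
                  ref = rep("A", n), alt = rep("G", n), dos = dos,
                  hap = hap, samples = samples, species = species,
                  hap_sample = if (!is.null(hap)) rep(samples, each = 2))
}

# phased genotype matrix from a haplotype matrix (sites x 2*individuals)
toy_gm_phased <- function(hap, species, pos = NULL, contig = "chr1") {
  n <- nrow(hap)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  samples <- names(species)
  genotype_matrix(contig = rep(contig, n), pos = pos,
                  ref = rep("A", n), alt = rep("G", n), hap = hap,
                  samples = samples, species = species,
                  hap_sample = rep(samples, each = 2))
}

# write a small VCF from text lines
write_mini_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

# two-deme island-model equilibrium sample for FST recovery checks; a small
# symmetric mutation rate keeps loci segregating so a stationary
# distribution exists (without it, conditioning on polymorphism after long
# drift inflates FST through differentially fixed loci)
sim_island_gm <- function(n_loci = 200, N = 500, m = 5e-4, n_gen = 3000,
                          n_sample = 25, u = 5e-5) {
  L <- n_loci * 4
  x1 <- rep(0.5, L)
  x2 <- rep(0.5, L)
  for (g in seq_len(n_gen)) {
    x1m <- (1 - m) * x1 + m * x2
    x2m <- (1 - m) * x2 + m * x1
    x1m <- (1 - u) * x1m + u * (1 - x1m)
    x2m <- (1 - u) * x2m + u * (1 - x2m)
    x1 <- rbinom(L, 2 * N, x1m) / (2 * N)
    x2 <- rbinom(L, 2 * N, x2m) / (2 * N)
  }
  pbar <- (x1 + x2) / 2
  seg <- which(pbar >= 0.05 & pbar <= 0.95)
  seg <- seg[seq_len(min(n_loci, length(seg)))]
  d1 <- sapply(x1[seg], function(p) rbinom(n_sample, 2, p))
  d2 <- sapply(x2[seg], function(p) rbinom(n_sample, 2, p))
  dos <- t(rbind(d1, d2))  # loci x (2*n_sample)
  species <- setNames(rep(c("deme1", "deme2"), each = n_sample),
                      c(paste0("a", seq_len(n_sample)),
                        paste0("b", seq_len(n_sample))))
  toy_gm(dos, species, pos = seq_along(seg) * 10000L)
}
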