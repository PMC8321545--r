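## Forward Wright-Fisher simulation of a radiating species complex.
##
## The engine (src/wf.cpp) evolves a set of lineages related by ordered split
## events.  Infinite-sites mutations live on continuous coordinates in
## [0, region_length) and are discretised to integer base pairs only at
## output.  One site per region may be under selection: a hard sweep from a
## new mutation, or an ancient balanced polymorphism (overdominance through
## the pre-split phase) later driven to alternative fixation in the focal
## species -- the standing-genetic-variation (SGV) scenario.

#' Demographic model for a set of lineages related by splits
#'
#' @param lineages data.frame with columns `name`, `parent` (NA for the root),
#'   `create_gen` (generation at which the lineage splits from its parent; 0
#'   for the root), `size` (diploid population size) and `sample_n` (diploids
#'   sampled at the end of the run; 0 for unsampled lineages).
#' @param n_gen total number of generations simulated; sampling happens at
#'   generation `n_gen`.
#' @param resize optional data.frame (`gen`, `lineage`, `size`) of step changes
#'   in lineage size.
#' @param generation_time_years generation time used only for reporting
#'   (default 2 years, the value commonly assumed for haplochromine cichlids).
#' @return an object of class `demography_config`.
#' @export
demography_config <- function(lineages, n_gen, resize = NULL,
                              generation_time_years = 2) {
  stopifnot(is.data.frame(lineages),
            all(c("name", "parent", "create_gen", "size", "sample_n") %in%
                  names(lineages)))
  if (anyDuplicated(lineages$name))
    stop("duplicated lineage names")
  if (is.na(lineages$parent[1]) == FALSE || lineages$create_gen[1] != 0)
    stop("first lineage must be the root (parent NA, create_gen 0)")
  cg <- lineages$create_gen[-1]
  if (length(cg) && any(diff(cg) < 0))
    stop("split generations must be non-decreasing in lineage order")
  if (length(cg) && any(duplicated(cg)))
    stop("split generations must be strictly increasing")
  bad <- setdiff(lineages$parent[-1], lineages$name)
  if (length(bad)) stop("unknown parent lineage: ", paste(bad, collapse = ", "))
  if (any(lineages$create_gen > n_gen & lineages$sample_n > 0))
    stop("sampled lineage created after sampling time")
  if (any(lineages$sample_n > .final_sizes(lineages, resize)))
    stop("sample_n exceeds lineage size at sampling time")
  structure(list(lineages = lineages, n_gen = as.integer(n_gen),
                 resize = resize,
                 generation_time_years = generation_time_years),
            class = "demography_config")
}

.final_sizes <- function(lineages, resize) {
  sz <- lineages$size
  if (!is.null(resize)) {
    for (i in seq_len(nrow(resize))) {
      j <- match(resize$lineage[i], lineages$name)
      sz[j] <- resize$size[i]
    }
  }
  sz
}

#' Mutation and recombination model
#'
#' The biological per-generation mutation rate for haplochromine cichlids is
#' about 3.5e-9 per bp; desk-scale runs hold the population-scaled rate
#' theta = 4*N*mu at a realistic value by scaling `mu` up while population
#' sizes are scaled down.
#'
#' @param mu mutations per bp per generation.
#' @param recomb_rate crossovers per bp per generation.
#' @param region_length region length in bp.
#' @export
mutation_config <- function(mu = 4e-6, recomb_rate = 2e-6,
                            region_length = 2e5) {
  stopifnot(mu >= 0, recomb_rate >= 0, region_length > 0)
  structure(list(mu = mu, recomb_rate = recomb_rate,
                 region_length = as.numeric(region_length)),
            class = "mutation_config")
}

#' Selection scenario for one simulated region
#'
#' @param mode one of `"neutral"`, `"de_novo_sweep"`, `"sgv_sweep"`.
#' @param selected_position position (bp) of the selected site; default the
#'   region midpoint.
#' @param s selection coefficient of the favoured homozygote in the
#'   directional phase.
#' @param h dominance of the favoured allele.
#' @param balancing_s heterozygote advantage during the ancestral balancing
#'   phase (`sgv_sweep` only).
#' @param target_lineages lineages in which the derived allele is favoured
#'   after their split.  For `sgv_sweep`, all other *focal* lineages are
#'   selected for the ancestral allele so that the focal species fix
#'   alternative allelic classes.
#' @param focal_lineages lineages forming the focal radiation (used by
#'   `sgv_sweep` to decide which lineages are driven to alternative fixation).
#' @param introduce_gen generation at which the de-novo mutation appears
#'   (default: creation generation of the target lineage, or the end of the
#'   radiation's split sequence for the root lineage).
#' @param stop_at_freq if > 0, a de-novo sweep run ends (and is sampled) as
#'   soon as the selected allele reaches this frequency in the target lineage,
#'   emulating an incomplete sweep.
#' @param init_freq initial frequency of the derived allele at the selected
#'   site in the root population (used by `sgv_sweep`, default 0.5, and by
#'   neutral standing-variant experiments).
#' @param recomb_suppress_radius bp radius around the selected site within
#'   which crossovers are thinned in `sgv_sweep` regions.  Ancient balanced
#'   haplotypes of the kind this scenario emulates are typically held
#'   together by local recombination suppression; 0 disables.
#' @param recomb_suppress_factor multiplier (< 1) applied to the local
#'   recombination rate inside the suppressed window.
#' @export
selection_scenario <- function(mode = c("neutral", "de_novo_sweep",
                                        "sgv_sweep"),
                               selected_position = NULL, s = 0.5, h = 0.5,
                               balancing_s = 0.5, target_lineages = NULL,
                               focal_lineages = NULL, introduce_gen = NULL,
                               stop_at_freq = 0, init_freq = 0.5,
                               recomb_suppress_radius = 5000,
                               recomb_suppress_factor = 0.02) {
  mode <- match.arg(mode)
  structure(list(mode = mode, selected_position = selected_position, s = s,
                 h = h, balancing_s = balancing_s,
                 target_lineages = target_lineages,
                 focal_lineages = focal_lineages,
                 introduce_gen = introduce_gen, stop_at_freq = stop_at_freq,
                 init_freq = init_freq,
                 recomb_suppress_radius = recomb_suppress_radius,
                 recomb_suppress_factor = recomb_suppress_factor),
            class = "selection_scenario")
}

#' Desk-scale demography of the Lake Victoria radiation with outgroup tiers
#'
#' Three focal species (default 6 diploids sampled each) plus four outgroup
#' lineages emulating the deeper tiers of the East African radiation: a Lake
#' Malawi representative (LM tier), a riverine lineage (HB tier), a Lake
#' Tanganyika lineage (LT tier) and a tilapiine used to root trees.  All
#' sizes and times are rescaled far below biological values so that a region
#' simulates in seconds; split depths are chosen so that outgroup tiers are
#' mostly lineage-sorted (tier gaps of 3 x 2N deep generations) while the
#' focal species retain the weak background differentiation characteristic
#' of a very recent radiation.
#'
#' @param n_focal diploid size of each focal species (and of the expanded
#'   pre-radiation ancestor).  The default keeps post-split drift small
#'   (T / 2N of about 0.06-0.11) so that genome-wide weighted FST between
#'   focal species lands near the 0.1-0.2 observed in very recent radiations,
#'   while hard sweeps still fix within the post-split time.
#' @param n_deep diploid size of the deep ancestral/outgroup lineages.
#' @param samples_focal,samples_outgroup diploids sampled per lineage.
#' @param expand_gen when the ancestral lineage expands from `n_deep` to
#'   `n_focal`: `"radiation"` (at the onset of the focal radiation; the
#'   short small-N stem keeps the focal clade lineage-sorted, best for
#'   gene-tree work) or `"deep_split"` (at the last outgroup split; the
#'   focal species then carry restored ancestral diversity, best for
#'   window-statistic work).
#' @export
radiation_demography <- function(n_focal = 500, n_deep = 40,
                                 samples_focal = 6, samples_outgroup = 2,
                                 expand_gen = c("radiation", "deep_split")) {
  expand_gen <- match.arg(expand_gen)
  gap <- 6 * n_deep          # 3 x 2N: deep tiers mostly sorted
  t_onil <- gap              # balancing phase precedes all splits
  t_nbri <- 2 * gap
  t_hbur <- 3 * gap
  t_acal <- 4 * gap          # root expands to n_focal here, so the focal
                             # radiation carries restored ancestral diversity
  t_rad  <- 5 * gap          # radiation onset
  t_lruf <- t_rad + 20
  n_gen  <- t_rad + 110
  lineages <- data.frame(
    name = c("HChi", "ONil", "NBri", "HBur", "ACal", "HSau", "LRuf"),
    parent = c(NA, "HChi", "HChi", "HChi", "HChi", "HChi", "HChi"),
    create_gen = c(0L, t_onil, t_nbri, t_hbur, t_acal, t_rad, t_lruf),
    size = c(n_deep, n_deep, n_deep, n_deep, n_deep, n_focal, n_focal),
    sample_n = c(samples_focal, samples_outgroup, samples_outgroup,
                 samples_outgroup, samples_outgroup, samples_focal,
                 samples_focal),
    stringsAsFactors = FALSE)
  resize <- data.frame(gen = if (expand_gen == "deep_split") t_acal else t_rad,
                       lineage = "HChi", size = n_focal,
                       stringsAsFactors = FALSE)
  dem <- demography_config(lineages, n_gen = n_gen, resize = resize)
  dem$focal <- c("HChi", "HSau", "LRuf")
  dem$tiers <- c(HChi = "focal", HSau = "focal", LRuf = "focal",
                 ACal = "LM", HBur = "HB", NBri = "LT", ONil = "outgroup")
  dem$radiation_gen <- t_rad
  dem$radiation_end <- t_lruf
  dem
}

#' Single-population demography (calibration runs)
#' @param N diploid population size.
#' @param n_gen generations simulated.
#' @param sample_n diploids sampled.
#' @export
single_population_demography <- function(N, n_gen, sample_n = N) {
  lineages <- data.frame(name = "pop", parent = NA, create_gen = 0L,
                         size = N, sample_n = sample_n,
                         stringsAsFactors = FALSE)
  demography_config(lineages, n_gen = n_gen)
}

## Translate a scenario into the engine's per-lineage regime schedule.
.build_regimes <- function(scn, dem) {
  ln <- dem$lineages$name
  idx <- function(x) match(x, ln) - 1L
  rows <- NULL
  add <- function(lineage, start, code, s, h)
    rbind(rows, c(idx(lineage), start, code, s, h))
  focal <- scn$focal_lineages %||% dem$focal %||% ln[1]
  if (scn$mode == "sgv_sweep") {
    rows <- add(ln[1], 0L, 1L, scn$balancing_s, 0.5)
    rad_end <- dem$radiation_end %||% max(dem$lineages$create_gen)
    for (f in focal) {
      start <- if (f == ln[1]) rad_end else
        dem$lineages$create_gen[match(f, ln)]
      code <- if (f %in% scn$target_lineages) 2L else 3L
      rows <- add(f, start, code, scn$s, scn$h)
    }
  } else if (scn$mode == "de_novo_sweep") {
    tgt <- scn$target_lineages[1]
    if (is.null(tgt)) stop("de_novo_sweep needs a target lineage")
    intro <- scn$introduce_gen %||% {
      cg <- dem$lineages$create_gen[match(tgt, ln)]
      if (cg > 0) cg else dem$radiation_end %||% 0L
    }
    rows <- add(tgt, intro, 2L, scn$s, scn$h)
    attr(rows, "introduce_gen") <- intro
  }
  if (is.null(rows)) rows <- matrix(numeric(0), ncol = 5)
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a set of genomic regions under a radiation demography
#'
#' Each scenario yields one region (an independent realisation of the same
#' demography).  True gamete phase is retained in the output.
#'
#' @param demography a [demography_config()].
#' @param mutation a [mutation_config()].
#' @param scenarios list of [selection_scenario()] objects, one per region.
#' @param seed integer seed; fixes all randomness, including engine seeds.
#' @param max_retries bounded retry count for establishment conditioning of
#'   de-novo sweeps (and survival of the balanced polymorphism).
#' @return object of class `radiation_sim`: `$regions` is a list of
#'   [genotype_matrix] objects (one per region, contig names `region001`,
#'   ...), `$truth` a data.frame of per-region truth records and `$genes` the
#'   simulated gene models.
#' @export
simulate_radiation <- function(demography, mutation, scenarios, seed,
                               max_retries = 100) {
  stopifnot(inherits(demography, "demography_config"),
            inherits(mutation, "mutation_config"))
  if (inherits(scenarios, "selection_scenario")) scenarios <- list(scenarios)
  set.seed(as.integer(seed))
  nr <- length(scenarios)
  engine_seeds <- sample.int(2^31 - 2, nr)
  lins <- demography$lineages
  resize <- demography$resize
  rmat <- if (is.null(resize)) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(resize$gen, match(resize$lineage, lins$name) - 1L, resize$size)
  }
  regions <- vector("list", nr)
  truth <- vector("list", nr)
  genes <- vector("list", nr)
  first_split <- if (nrow(lins) > 1) min(lins$create_gen[-1]) else NA

  for (i in seq_len(nr)) {
    scn <- scenarios[[i]]
    stopifnot(inherits(scn, "selection_scenario"))
    if (!is.null(scn$target_lineages)) {
      bad <- setdiff(scn$target_lineages, lins$name)
      if (length(bad))
        stop("scenario ", i, " references unknown lineage: ",
             paste(bad, collapse = ", "))
      if (any(lins$sample_n[match(scn$target_lineages, lins$name)] == 0))
        stop("scenario ", i, " targets an unsampled lineage")
    }
    L <- mutation$region_length
    sel_pos <- scn$selected_position %||% (L / 2)
    regimes <- .build_regimes(scn, demography)
    mode_code <- switch(scn$mode, neutral = 0L, de_novo_sweep = 1L,
                        sgv_sweep = 2L)
    intro <- attr(regimes, "introduce_gen") %||% 0L
    tgt_idx <- if (!is.null(scn$target_lineages))
      match(scn$target_lineages[1], lins$name) - 1L else 0L
    supp_r <- if (scn$mode == "sgv_sweep") scn$recomb_suppress_radius else 0
    init_f <- if (scn$mode == "sgv_sweep" ||
                  (scn$mode == "neutral" && !is.null(scn$selected_position)))
      scn$init_freq else 0
    guard <- if (scn$mode == "sgv_sweep")
      (demography$radiation_gen %||% demography$n_gen) else 0L

    res <- wf_simulate_cpp(
      lin_parent = match(lins$parent, lins$name) - 1L,
      lin_create = as.integer(lins$create_gen),
      lin_size = as.integer(lins$size), resize = rmat,
      sample_n = as.integer(lins$sample_n), n_gen = demography$n_gen,
      L = L, mu = mutation$mu, rec = mutation$recomb_rate,
      supp_center = sel_pos, supp_radius = supp_r,
      supp_factor = scn$recomb_suppress_factor,
      sel_mode = if (mode_code == 0L && init_f == 0) -1L else mode_code,
      sel_pos = sel_pos, init_freq = init_f,
      introduce_gen = as.integer(intro), introduce_lineage = tgt_idx,
      regimes = regimes, stop_at_freq = scn$stop_at_freq,
      sgv_guard_gen = as.integer(guard), max_retries = max_retries,
      seed = engine_seeds[i])
    if (!isTRUE(res$ok))
      stop("scenario ", i, " (", scn$mode, "): selected allele lost after ",
           res$retries, " retries")

    contig <- sprintf("region%03d", i)
    regions[[i]] <- .sim_to_genotype_matrix(res, lins, contig, L)
    sel_bp <- attr(regions[[i]], "selected_bp")
    sel_bp <- if (length(sel_bp)) sel_bp else as.integer(floor(sel_pos) + 1)
    freq <- res$sel_freq
    names(freq) <- lins$name
    fixed_in <- names(freq)[!is.na(freq) & freq >= 0.95]
    truth[[i]] <- data.frame(
      region = contig, mode = scn$mode,
      selected_pos = if (scn$mode == "neutral") NA_integer_ else sel_bp,
      origin_depth = switch(scn$mode, neutral = NA_character_,
                            de_novo_sweep = "post_split",
                            sgv_sweep = "pre_radiation"),
      origin_gen = switch(scn$mode, neutral = NA_integer_,
                          de_novo_sweep = as.integer(intro), sgv_sweep = 0L),
      first_split_gen = first_split,
      target_lineages = paste(scn$target_lineages, collapse = ","),
      sel_freq = paste(sprintf("%s=%.3f", names(freq)[!is.na(freq)],
                               freq[!is.na(freq)]), collapse = ";"),
      fixed_lineages = paste(fixed_in, collapse = ","),
      retries = res$retries, stringsAsFactors = FALSE)
    genes[[i]] <- .sim_gene_model(contig, sel_bp, L, i)
  }
  structure(list(regions = regions, truth = do.call(rbind, truth),
                 genes = do.call(rbind, genes), demography = demography,
                 mutation = mutation, seed = seed),
            class = "radiation_sim")
}

## A simple two-exon gene model centred on the (putatively) selected site.
.sim_gene_model <- function(contig, sel_bp, L, i) {
  g0 <- max(0L, as.integer(sel_bp) - 5000L)
  g1 <- min(as.integer(L), as.integer(sel_bp) + 5000L)
  gene <- sprintf("gene_%s", contig)
  data.frame(
    gene = gene, contig = contig,
    start = c(g0, g0, g1 - 2000L),
    end = c(g1, g0 + 2000L, g1),
    feature = c("gene", "exon", "exon"), stringsAsFactors = FALSE)
}

## Engine output -> genotype_matrix (positions discretised to 1-based bp,
## collisions resolved by +1 shifting; random distinct ref/alt bases).
.sim_to_genotype_matrix <- function(res, lins, contig, L) {
  pos <- floor(res$positions) + 1
  if (length(pos) > 1)
    for (k in 2:length(pos)) if (pos[k] <= pos[k - 1]) pos[k] <- pos[k - 1] + 1
  n_sites <- length(pos)
  hap <- res$alleles
  lin_names <- lins$name[res$hap_lineage + 1]
  ind <- res$hap_individual
  samples <- unique(sprintf("%s_%d", lin_names, ind + 1))
  hap_sample <- sprintf("%s_%d", lin_names, ind + 1)
  species <- setNames(sub("_[0-9]+$", "", samples), samples)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  gm <- genotype_matrix(
    contig = rep(contig, n_sites), pos = as.integer(pos), ref = ref,
    alt = unname(alt), hap = hap, samples = samples, species = species,
    hap_sample = hap_sample)
  sel_rows <- which(res$is_selected_site == 1)
  attr(gm, "selected_bp") <- as.integer(pos[sel_rows])
  gm
}

#' Write simulation outputs as plain-text files
#'
#' Emits one VCF (contigs = regions, phased GT), a BED6 file of gene models
#' (name field `gene;feature`), a sample-to-species map TSV, the species tree
#' in newick format and the per-region truth table.
#'
#' @param sim result of [simulate_radiation()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named list of file paths.
#' @export
write_outputs <- function(sim, out_dir) {
  stopifnot(inherits(sim, "radiation_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- do.call(rbind_genotype_matrix, sim$regions)
  paths <- list(
    vcf = file.path(out_dir, "simulated.vcf"),
    genes = file.path(out_dir, "genes.bed"),
    species_map = file.path(out_dir, "species_map.tsv"),
    tree = file.path(out_dir, "species_tree.nwk"),
    truth = file.path(out_dir, "truth.tsv"))
  write_vcf(gm, paths$vcf,
            contig_lengths = setNames(
              rep(sim$mutation$region_length, length(sim$regions)),
              vapply(sim$regions, function(r) r$contig[1], "")))
  write_gene_models(sim$genes, paths$genes)
  write.table(data.frame(sample = gm$samples,
                         species = unname(gm$species[gm$samples])),
              paths$species_map, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(.species_tree_newick(sim$demography), paths$tree)
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

## Newick species tree from the split order (branch lengths in generations).
.species_tree_newick <- function(dem) {
  lins <- dem$lineages
  n_gen <- dem$n_gen
  ## build by successive nesting from the most recent split backwards
  ord <- order(lins$create_gen[-1], decreasing = TRUE) + 1L
  tip <- lins$name[1]
  tip_str <- tip
  last <- n_gen
  for (j in ord) {
    dt <- lins$create_gen[j]
    tip_str <- sprintf("(%s:%d,%s:%d)", tip_str, max(0L, last - dt),
                       lins$name[j], n_gen - dt)
    last <- dt
  }
  paste0(tip_str, ";")
}
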