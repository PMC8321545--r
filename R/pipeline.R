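## End-to-end pipeline: simulate (or load) -> site filter -> window
## statistics -> HDR scan -> iHS -> allelic-origin classification, with
## plain-text intermediates, a JSON run report and a log of every realised
## threshold.

#' Pipeline configuration
#'
#' Defaults follow the canonical genome-scan settings: 10-kb windows with
#' 2-kb increments, top 0.5% outlier quantiles for FST and dXY, HWE exact
#' alpha 0.001, MAF 0.05 with 50/5/0.1 LD pruning for the structure path,
#' iHS extreme mass 1%, 100 bootstrap replicates with support threshold 60,
#' and 10-kb gene flanks.
#'
#' @param out_dir run directory.
#' @param seed integer seed controlling every stage.
#' @param simulate list describing the simulation (see
#'   [demo_pipeline_config()]) or NULL to read `vcf`/`species_map`/`genes`
#'   inputs.
#' @param vcf,species_map,genes,truth input paths (when not simulating).
#' @param focal_species the three focal species for window scans.
#' @param tiers named taxon -> tier map for origin classification.
#' @param window,step window grid (bp).
#' @param hdr_quantile,dxy_quantile outlier quantiles.
#' @param hwe_alpha,hwe_mode,maf_min,ld_window,ld_step,ld_r2 filter and
#'   structure-path settings.
#' @param ihs_crit,ihs_maf,ihs_bins iHS settings.
#' @param n_boot,support_min tree settings.
#' @param flank gene flank (bp).
#' @param origin_genes gene selection for the origin stage:
#'   `"candidates"` (genes mapped to HDRs, the default) or `"all"` (every
#'   gene in the gene models with enough data; useful when the origin module
#'   is the object of study).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "filter", "winstats", "pca", "scan", "ihs", "origin")`;
#'   earlier stages are loaded from persisted intermediates when skipped.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = NULL, vcf = NULL,
                            species_map = NULL, genes = NULL, truth = NULL,
                            focal_species = c("HChi", "HSau", "LRuf"),
                            tiers = c(HChi = "focal", HSau = "focal",
                                      LRuf = "focal", ACal = "LM",
                                      HBur = "HB", NBri = "LT",
                                      ONil = "outgroup"),
                            window = 10000, step = 2000,
                            hdr_quantile = 0.995, dxy_quantile = 0.995,
                            hwe_alpha = 0.001, hwe_mode = "pooled",
                            maf_min = 0.05, ld_window = 50, ld_step = 5,
                            ld_r2 = 0.1, ihs_crit = 0.01, ihs_maf = 0.05,
                            ihs_bins = 50, n_boot = 100, support_min = 60,
                            flank = 10000,
                            origin_genes = c("candidates", "all"),
                            stages = c("simulate", "filter", "winstats",
                                       "pca", "scan", "ihs", "origin")) {
  origin_genes <- match.arg(origin_genes)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Demo pipeline configuration: 3 focal species, 20 regions, 5 + 5 sweeps
#'
#' The packaged demonstration world: a [radiation_demography()] with three
#' focal species of 6 diploids each plus outgroup tiers; 20 regions of 600
#' kb of which 5 carry de-novo hard sweeps (all targeting *H. chilotes*,
#' giving chilotes-specific differentiation), 5 carry sweeps from ancient
#' standing variation (all targeting *L. rufus*, whose real-data HDRs are
#' dominated by high-dXY SGV signals) and 10 are neutral.  Concentrating
#' each sweep type on one species keeps one species pair free of
#' the much stronger SGV windows, so that the top-0.5% outlier budget can
#' reach the physically weaker one-sided de-novo sweep windows; the region
#' count/length trades simulation time against outlier-budget resolution.
#' The HWE filter runs per species here (the pooled test removes exactly
#' the strongly differentiated sites the scan is after; see the methods
#' vignette).
#'
#' @param out_dir,seed passed to [pipeline_config()].
#' @param n_neutral,n_de_novo,n_sgv region counts per scenario class.
#' @param region_length region length in bp.
#' @param mu,recomb_rate per-bp per-generation rates.
#' @param n_focal,n_deep,expand_gen passed to [radiation_demography()];
#'   the demo expands at the deep split so focal windows carry enough SNPs.
#' @param stages stages to run.
#' @param origin_genes see [pipeline_config()].
#' @export
demo_pipeline_config <- function(out_dir, seed = 1, n_neutral = 10,
                                 n_de_novo = 5, n_sgv = 5,
                                 region_length = 6e5, mu = 2.5e-6,
                                 recomb_rate = 2e-6, n_focal = 400,
                                 n_deep = 25, expand_gen = "deep_split",
                                 stages = c("simulate", "filter", "winstats",
                                            "pca", "scan", "ihs", "origin"),
                                 origin_genes = "candidates") {
  scen <- c(
    replicate(n_de_novo,
              selection_scenario("de_novo_sweep", target_lineages = "HChi"),
              simplify = FALSE),
    replicate(n_sgv,
              selection_scenario("sgv_sweep", target_lineages = "LRuf",
                                 s = 0.3),
              simplify = FALSE),
    replicate(n_neutral, selection_scenario("neutral"), simplify = FALSE))
  pipeline_config(
    out_dir = out_dir, seed = seed,
    simulate = list(
      demography = radiation_demography(n_focal = n_focal, n_deep = n_deep,
                                        expand_gen = expand_gen),
      mutation = mutation_config(mu = mu, recomb_rate = recomb_rate,
                                 region_length = region_length),
      scenarios = scen),
    hwe_mode = "per_species", stages = stages, origin_genes = origin_genes)
}

#' Run the analysis pipeline
#'
#' Deterministic given `cfg$seed`.  Writes plain-text intermediates and a
#' JSON report (`report.json`) with per-stage counts and every realised
#' threshold into `cfg$out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed)
  logf <- file.path(cfg$out_dir, "log.txt")
  cat("", file = logf)
  note <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                            append = TRUE)
  set.seed(cfg$seed)
  stage_seeds <- sample.int(2^31 - 2, 8)
  st <- list()  # pipeline state

  ## --- simulate or load inputs ------------------------------------------
  if ("simulate" %in% cfg$stages && !is.null(cfg$simulate)) {
    set.seed(stage_seeds[1])
    sim <- simulate_radiation(cfg$simulate$demography, cfg$simulate$mutation,
                              cfg$simulate$scenarios, seed = stage_seeds[1])
    write_outputs(sim, cfg$out_dir)
    st$gm <- do.call(rbind_genotype_matrix, sim$regions)
    st$truth <- sim$truth
    st$genes <- sim$genes
    st$contig_lengths <- setNames(
      rep(cfg$simulate$mutation$region_length, length(sim$regions)),
      vapply(sim$regions, function(r) r$contig[1], ""))
    report$simulate <- list(n_regions = length(sim$regions),
                            n_sites = n_sites(st$gm),
                            modes = table(sim$truth$mode))
    note("simulate: %d regions, %d variant sites", length(sim$regions),
         n_sites(st$gm))
  } else {
    vcf <- cfg$vcf %||% file.path(cfg$out_dir, "simulated.vcf")
    smap <- cfg$species_map %||% file.path(cfg$out_dir, "species_map.tsv")
    if (!file.exists(smap))
      stop("pipeline aborted at stage 'filter': species map not found (",
           smap, ")")
    st$gm <- read_vcf(vcf, smap)
    genes_path <- cfg$genes %||% file.path(cfg$out_dir, "genes.bed")
    if (file.exists(genes_path)) st$genes <- read_gene_models(genes_path)
    truth_path <- cfg$truth %||% file.path(cfg$out_dir, "truth.tsv")
    if (file.exists(truth_path))
      st$truth <- read.table(truth_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    st$contig_lengths <- attr(st$gm, "contig_lengths") %||%
      tapply(st$gm$pos, st$gm$contig, max)
  }

  ## --- site filter -------------------------------------------------------
  if ("filter" %in% cfg$stages) {
    fc <- filter_config(hwe_alpha = cfg$hwe_alpha, hwe_mode = cfg$hwe_mode)
    fl <- filter_sites(st$gm, fc)
    st$filtered <- fl$genotypes
    write.table(fl$log, file.path(cfg$out_dir, "filter_log.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_vcf(st$filtered, file.path(cfg$out_dir, "filtered.vcf"),
              contig_lengths = st$contig_lengths)
    report$filter <- list(n_in = n_sites(st$gm),
                          n_out = n_sites(st$filtered),
                          dropped_by_rule = table(fl$log$rule))
    note("filter: %d -> %d sites (hwe_mode=%s)", n_sites(st$gm),
         n_sites(st$filtered), cfg$hwe_mode)
  } else if (file.exists(file.path(cfg$out_dir, "filtered.vcf"))) {
    st$filtered <- read_vcf(file.path(cfg$out_dir, "filtered.vcf"),
                            data.frame(names(st$gm$species),
                                       unname(st$gm$species)))
  } else st$filtered <- st$gm

  ## --- window statistics -------------------------------------------------
  ws_path <- file.path(cfg$out_dir, "window_stats.tsv")
  if ("winstats" %in% cfg$stages) {
    st$stats <- window_stats(st$filtered,
                             contig_lengths = st$contig_lengths,
                             species = cfg$focal_species,
                             window = cfg$window, step = cfg$step)
    gf <- attr(st$stats, "genome_fst")
    write.table(st$stats, ws_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$winstats <- list(n_windows = nrow(st$stats),
                            genome_fst = as.list(gf))
    for (k in names(gf)) note("genome-wide weighted FST %s = %.6f", k, gf[k])
  } else if (file.exists(ws_path)) {
    st$stats <- read.table(ws_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    class(st$stats) <- c("window_stats", "data.frame")
  }

  ## --- structure path (MAF + LD pruning + PCA) --------------------------
  if ("pca" %in% cfg$stages) {
    set.seed(stage_seeds[3])
    focal_gm <- gm_subset(st$filtered,
                          samples = st$filtered$samples[
                            st$filtered$species %in% cfg$focal_species])
    mf <- filter_sites(focal_gm, filter_config(hwe_alpha = NA,
                                               maf_min = cfg$maf_min))
    kept <- ld_prune(mf$genotypes, cfg$ld_window, cfg$ld_step, cfg$ld_r2)
    pruned <- gm_subset(mf$genotypes, kept)
    pca <- pca_genotypes(pruned)
    write.table(data.frame(sample = rownames(pca$coords),
                           species = unname(pruned$species), pca$coords),
                file.path(cfg$out_dir, "pca.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$pca <- list(n_snps_maf = n_sites(mf$genotypes),
                       n_snps_pruned = length(kept),
                       explained = pca$explained[1:3])
    note("pca: %d SNPs after MAF, %d after LD pruning",
         n_sites(mf$genotypes), length(kept))
  }

  ## --- HDR scan ----------------------------------------------------------
  if ("scan" %in% cfg$stages) {
    pairs <- combn(cfg$focal_species, 2)
    hdr_list <- list()
    for (k in seq_len(ncol(pairs))) {
      key <- paste(pairs[, k], collapse = "_")
      h <- call_hdrs(st$stats, key, cfg$hdr_quantile)
      h <- sweep_flag(st$stats, h, key, cfg$dxy_quantile)
      note("HDR threshold %s: fst %.6f, dxy %.6f", key,
           attr(h, "threshold"), attr(h, "dxy_threshold"))
      hdr_list[[key]] <- h
    }
    hdr_list <- assign_specificity(hdr_list)
    st$hdrs <- do.call(rbind, lapply(hdr_list, function(h)
      h[, c("contig", "start", "end", "pair", "threshold", "peak_fst",
            "peak_dxy", "sweep", "label", "n_windows")]))
    rownames(st$hdrs) <- NULL
    write.table(st$hdrs, file.path(cfg$out_dir, "hdrs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_bed(st$hdrs, file.path(cfg$out_dir, "hdrs.bed"))
    if (!is.null(st$genes)) {
      st$candidates <- map_genes_to_hdrs(st$hdrs, st$genes, stats = st$stats,
                                         flank = cfg$flank)
      anno <- annotate_differentiated_snps(st$filtered, st$candidates,
                                           st$genes, flank = cfg$flank)
      write.table(st$candidates, file.path(cfg$out_dir, "candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(anno$snps, file.path(cfg$out_dir, "snp_annotations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$scan <- list(
        hdr_per_pair = table(st$hdrs$pair),
        labels = table(st$hdrs$label),
        n_candidate_genes = nrow(st$candidates),
        n_coding_diff = sum(anno$genes$coding_diff, na.rm = TRUE))
      note("scan: %d HDRs, %d candidate genes", nrow(st$hdrs),
           nrow(st$candidates))
    }
  } else if (file.exists(file.path(cfg$out_dir, "hdrs.tsv"))) {
    st$hdrs <- read.table(file.path(cfg$out_dir, "hdrs.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
    if (file.exists(file.path(cfg$out_dir, "candidates.tsv")))
      st$candidates <- read.table(file.path(cfg$out_dir, "candidates.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }

  ## --- iHS ---------------------------------------------------------------
  if ("ihs" %in% cfg$stages) {
    for (sp in cfg$focal_species) {
      tbl <- scan_species(st$filtered, sp, anc = "ref",
                          maf_floor = cfg$ihs_maf, n_bins = cfg$ihs_bins,
                          crit = cfg$ihs_crit)
      write.table(tbl, file.path(cfg$out_dir, paste0("ihs_", sp, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      report$ihs[[sp]] <- list(n_cores = nrow(tbl),
                               n_extreme = sum(tbl$extreme))
      note("ihs %s: %d cores, %d extreme", sp, nrow(tbl), sum(tbl$extreme))
    }
  }

  ## --- allelic-origin classification ------------------------------------
  origin_set <- if (identical(cfg$origin_genes, "all") &&
                    !is.null(st$genes)) {
    g <- st$genes[st$genes$feature == "gene", , drop = FALSE]
    g$max_dxy <- .genes_max_dxy(st$stats, g)
    g
  } else st$candidates
  if ("origin" %in% cfg$stages && !is.null(origin_set) &&
      nrow(origin_set)) {
    set.seed(stage_seeds[6])
    calls <- list()
    for (i in seq_len(nrow(origin_set))) {
      gene <- origin_set[i, ]
      gm_gene <- gm_subset(st$filtered,
                           which(st$filtered$contig == gene$contig))
      call <- tryCatch({
        aln <- build_gene_alignment(gm_gene, gene, mode = "gene_nt")
        og <- names(cfg$tiers)[cfg$tiers == "outgroup"][1]
        tree <- nj_tree_with_bootstrap(aln, n_boot = cfg$n_boot,
                                       outgroup = og)
        ape::write.tree(tree, file.path(cfg$out_dir,
                                        paste0("tree_", gene$gene, ".nwk")))
        classify_origin(tree, cfg$tiers, support_min = cfg$support_min)
      }, gene_skipped = function(e)
        list(origin = "skipped", depth = "n/a", support = NA_real_,
             monophyletic = NA))
      calls[[i]] <- data.frame(gene = gene$gene, origin = call$origin,
                               depth = call$depth, support = call$support,
                               monophyletic = call$monophyletic,
                               max_dxy = gene$max_dxy,
                               stringsAsFactors = FALSE)
    }
    st$origins <- do.call(rbind, calls)
    write.table(st$origins, file.path(cfg$out_dir, "origin_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    mw <- compare_dxy_by_origin(st$origins)
    report$origin <- list(tally = table(st$origins$origin),
                          depth = table(st$origins$depth),
                          mann_whitney = mw)
    note("origin: %s; Mann-Whitney p = %.4g (SGV median %.4g, new %.4g)",
         paste(names(table(st$origins$origin)), table(st$origins$origin),
               sep = "=", collapse = ", "),
         mw$p, mw$median_sgv, mw$median_new)
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(c(st, list(report = report)))
}

## max window dXY (over all dXY columns) per gene interval
.genes_max_dxy <- function(stats, genes) {
  dxy_cols <- grep("^dxy_", names(stats), value = TRUE)
  lv <- union(unique(stats$contig), unique(genes$contig))
  wgr <- GenomicRanges::GRanges(factor(stats$contig, lv),
                                IRanges::IRanges(stats$start + 1, stats$end))
  ggr <- GenomicRanges::GRanges(factor(genes$contig, lv),
                                IRanges::IRanges(genes$start + 1, genes$end))
  ov <- GenomicRanges::findOverlaps(ggr, wgr)
  vapply(seq_len(nrow(genes)), function(i) {
    wins <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    if (!length(wins)) return(NA_real_)
    vals <- unlist(stats[wins, dxy_cols, drop = FALSE])
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }, 0)
}

.write_bed <- function(df, path) {
  bed <- data.frame(df$contig, df$start, df$end,
                    paste(df$pair, df$label, sep = ";"), 0L, "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `filter`, `winstats`, `scan`, `ihs`, `origin`,
#' `all`.  `all` runs the demo pipeline (or a JSON config) end to end.
#' Returns exit status: 0 ok, 1 user error, 2 internal error.
#'
#' @param args character vector of command-line arguments.
#' @export
sgvscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: sgvscan {simulate|filter|winstats|scan|ihs|origin|all} [options]"
  if (!length(args)) {
    message(usage)
    return(1L)
  }
  cmd <- args[1]
  rest <- args[-1]
  run <- function(stages) {
    opts <- optparse::parse_args(
      optparse::OptionParser(option_list = list(
        optparse::make_option("--config", type = "character",
                              default = NULL),
        optparse::make_option("--seed", type = "integer", default = 1L),
        optparse::make_option("--out", type = "character",
                              default = "sgvscan_run"))),
      args = rest)
    cfg <- if (is.null(opts$config)) {
      demo_pipeline_config(opts$out, seed = opts$seed, stages = stages)
    } else {
      raw <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
      do.call(pipeline_config,
              c(list(out_dir = opts$out, seed = opts$seed,
                     stages = stages), raw))
    }
    run_pipeline(cfg)
    0L
  }
  tryCatch({
    switch(cmd,
           all = run(c("simulate", "filter", "winstats", "pca", "scan",
                       "ihs", "origin")),
           simulate = run("simulate"),
           filter = run("filter"),
           winstats = run("winstats"),
           scan = run("scan"),
           ihs = run("ihs"),
           origin = run("origin"),
           {
             message(usage)
             1L
           })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("not found|missing|unknown|usage", conditionMessage(e))) 1L
    else 2L
  })
}
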