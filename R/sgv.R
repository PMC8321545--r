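## Classification of divergent alleles as standing genetic variation (SGV)
## versus new mutation, via gene-tree / species-tree discordance.
##
## For each candidate gene, per-taxon consensus sequences over the gene's
## region are aligned by construction (reference coordinates), a
## neighbour-joining tree on Jukes-Cantor distances is built with column
## bootstrap supports, and the focal-radiation taxa are tested for
## monophyly: a supported non-monophyletic arrangement -- an outgroup-tier
## taxon nested among focal alleles -- is the SGV diagnostic, with the
## origin depth given by the deepest intruding tier.

.TIER_DEPTH <- c(outgroup = 4, LT = 3, HB = 2, LM = 1, focal = 0)

#' Build a gene alignment of per-taxon consensus sequences
#'
#' Sequences are reference-coordinate aligned: each taxon's sequence has the
#' major allele (ties broken towards the reference allele) at every variant
#' site and a constant filler base at invariant positions.  Columns at which
#' any taxon has no called genotype are removed (mirroring the use of sites
#' without deletions or missing data), and the removal is logged.
#'
#' @param gm a [genotype_matrix] whose species are the tree taxa.
#' @param gene one row of a gene table (list/data.frame with contig, start,
#'   end) or a numeric `c(start, end)` with `contig` given separately.
#' @param mode `"gene_nt"` (whole interval) or `"exon_nt"` (exon
#'   sub-intervals only; requires `gene_models`).
#' @param gene_models gene-model table (for `exon_nt`).
#' @param min_taxa minimum taxa retained (default 4); fewer raises an error
#'   of class `gene_skipped`.
#' @param per_haplotype if TRUE, emit one sequence per haplotype instead of
#'   per-species consensus (taxa named `<species>_<i>_h<1|2>`).
#' @return object of class `gene_alignment`: character matrix of sequences
#'   plus bookkeeping attributes.
#' @export
build_gene_alignment <- function(gm, gene, mode = c("gene_nt", "exon_nt"),
                                 gene_models = NULL, min_taxa = 4,
                                 per_haplotype = FALSE) {
  mode <- match.arg(mode)
  ct <- gene$contig
  intervals <- if (mode == "gene_nt") {
    data.frame(start = gene$start, end = gene$end)
  } else {
    ex <- gene_models[gene_models$gene == gene$gene &
                        gene_models$feature == "exon", , drop = FALSE]
    if (!nrow(ex)) stop("no exon models for gene ", gene$gene)
    ex[order(ex$start), c("start", "end")]
  }
  width <- sum(intervals$end - intervals$start)
  ## offsets of each variant site within the concatenated interval
  site_idx <- integer(0)
  site_off <- integer(0)
  off0 <- 0
  for (r in seq_len(nrow(intervals))) {
    s <- which(gm$contig == ct & gm$pos > intervals$start[r] &
                 gm$pos <= intervals$end[r])
    site_idx <- c(site_idx, s)
    site_off <- c(site_off, off0 + (gm$pos[s] - intervals$start[r]))
    off0 <- off0 + (intervals$end[r] - intervals$start[r])
  }
  taxa_species <- unique(gm$species)
  if (per_haplotype) {
    cols_of <- split(seq_along(gm$hap_sample), gm$hap_sample)
    taxa <- unlist(lapply(gm$samples, function(s) paste0(s, "_h", 1:2)))
    alle <- sapply(gm$samples, function(s)
      gm$hap[site_idx, cols_of[[s]], drop = FALSE], simplify = FALSE)
    alle <- do.call(cbind, alle)  # sites x haplotypes, 0/1/NA
    taxon_species <- rep(gm$species[gm$samples], each = 2)
  } else {
    taxa <- taxa_species
    freq <- allele_freq(gm_subset(gm, site_idx), taxa_species)
    alle <- matrix(NA_integer_, length(site_idx), length(taxa))
    alle[!is.na(freq) & freq > 0.5] <- 1L
    alle[!is.na(freq) & freq <= 0.5] <- 0L  # ties -> reference allele
    taxon_species <- taxa_species
  }
  drop_col <- if (length(site_idx)) apply(is.na(alle), 1, any) else logical(0)
  keep <- which(!drop_col)
  seqs <- matrix("a", length(taxa), width,
                 dimnames = list(taxa, NULL))
  for (j in seq_along(taxa)) {
    refs <- tolower(gm$ref[site_idx[keep]])
    alts <- tolower(gm$alt[site_idx[keep]])
    seqs[j, site_off[keep]] <- ifelse(alle[keep, j] == 1L, alts, refs)
  }
  if (any(drop_col))  # excise fully, as with deletion columns
    seqs <- seqs[, -site_off[drop_col], drop = FALSE]
  if (nrow(seqs) < min_taxa) {
    cond <- structure(class = c("gene_skipped", "error", "condition"),
                      list(message = sprintf(
                        "gene has %d taxa after filtering (need >= %d)",
                        nrow(seqs), min_taxa), call = sys.call()))
    stop(cond)
  }
  structure(seqs, class = c("gene_alignment", class(seqs)),
            species = setNames(taxon_species, taxa),
            removed_columns = sum(drop_col),
            variant_offsets = site_off[keep], gene = gene$gene %||% NA,
            mode = mode)
}

#' Neighbour-joining tree from a distance matrix
#'
#' The tree engine behind [nj_tree_with_bootstrap()]; exposed so the
#' distance-level behaviour (e.g. recovery of additive splits) can be
#' exercised directly.
#'
#' @param D distance matrix (`dist` or symmetric matrix with dimnames).
#' @return unrooted `phylo`.
#' @export
nj_from_dist <- function(D) ape::nj(stats::as.dist(D))

#' Neighbour-joining tree with column-bootstrap supports
#'
#' Jukes-Cantor distances (pairs with undefined JC correction, p-distance >=
#' 0.75, fall back to the raw p-distance, logged via an attribute) are fed
#' to neighbour joining; internal-edge supports are the percentage of
#' column-resampled replicate trees containing each bipartition.  The tree
#' is rooted on the outgroup.  Uses R's RNG: set a seed for reproducible
#' supports.
#'
#' @param aln a [build_gene_alignment()] result (or plain character matrix
#'   of aligned sequences, rows = taxa).
#' @param n_boot bootstrap replicates (default 100).
#' @param outgroup outgroup taxon label used to root the tree.
#' @return rooted `phylo` object; `node.label` holds percent supports.
#' @export
nj_tree_with_bootstrap <- function(aln, n_boot = 100, outgroup) {
  seqs <- unclass(aln)
  stopifnot(is.matrix(seqs), nrow(seqs) >= 4, ncol(seqs) >= 1,
            outgroup %in% rownames(seqs))
  dna <- ape::as.DNAbin(seqs)
  D <- .jc_dist(dna)
  tree <- nj_from_dist(D)
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(ncol(seqs), ncol(seqs), replace = TRUE)
    Db <- .jc_dist(ape::as.DNAbin(seqs[, idx, drop = FALSE]))
    boots[[b]] <- nj_from_dist(Db)
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- as.character(round(100 * counts / n_boot))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  attr(rooted, "jc_fallback") <- attr(D, "jc_fallback")
  rooted
}

## JC69 distances with per-pair fallback to raw p-distance where the
## correction is undefined.
.jc_dist <- function(dna) {
  D <- suppressWarnings(ape::dist.dna(dna, model = "JC69",
                                      pairwise.deletion = FALSE))
  bad <- !is.finite(D)
  if (any(bad)) {
    Draw <- ape::dist.dna(dna, model = "raw", pairwise.deletion = FALSE)
    D[bad] <- Draw[bad]
  }
  attr(D, "jc_fallback") <- sum(bad)
  D
}

## tips under each node, accumulated over a postorder edge traversal
.node_tips <- function(tree) {
  nt <- length(tree$tip.label)
  out <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) out[[i]] <- i
  edge <- reorder(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    ch <- edge[k, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Classify a gene's allelic origin from its tree
#'
#' If the focal-radiation taxa are monophyletic and the focal clade's
#' bootstrap support reaches `support_min`, the divergent alleles are called
#' `new_mutation`.  If a non-focal taxon is nested inside the smallest clade
#' containing all focal taxa, the supports consulted are those of the
#' smallest clades jointly containing each intruder and part of the focal
#' taxa; with support >= `support_min` the call is `SGV`, with the origin
#' depth given by the deepest supported intruding tier (`before_LT` >
#' `before_HB` > `before_LM`).  Anything else is `unresolved`.
#'
#' @param tree rooted `phylo` with percent supports in `node.label` (see
#'   [nj_tree_with_bootstrap()]).
#' @param lineage_map named character vector taxon -> tier, tiers in
#'   `c("focal", "LM", "HB", "LT", "outgroup")`.
#' @param support_min minimum bootstrap percent (default 60).
#' @return list of class `origin_call`: origin, depth, support, monophyletic.
#' @export
classify_origin <- function(tree, lineage_map, support_min = 60) {
  og <- names(lineage_map)[lineage_map == "outgroup"]
  og <- intersect(og, tree$tip.label)
  if (!length(og)) stop("outgroup absent from tree")
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = og[1], resolve.root = TRUE,
                      edgelabel = TRUE)
  focal <- intersect(names(lineage_map)[lineage_map == "focal"],
                     tree$tip.label)
  if (length(focal) < 2) stop("need >= 2 focal taxa in tree")
  nt <- length(tree$tip.label)
  tips <- .node_tips(tree)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  node_support <- function(nd) {
    if (nd <= nt) return(NA_real_)
    supp[nd - nt]
  }
  focal_idx <- match(focal, tree$tip.label)
  mrca <- ape::getMRCA(tree, focal)
  clade_tips <- tree$tip.label[tips[[mrca]]]
  out <- function(origin, depth, support, mono)
    structure(list(origin = origin, depth = depth, support = support,
                   monophyletic = mono), class = "origin_call")
  if (setequal(clade_tips, focal)) {
    s <- node_support(mrca)
    if (!is.na(s) && s >= support_min)
      return(out("new_mutation", "n/a", s, TRUE))
    return(out("unresolved", "n/a", s, TRUE))
  }
  intruders <- setdiff(clade_tips, focal)
  parent_of <- setNames(tree$edge[, 1], tree$edge[, 2])
  qual_support <- numeric(0)
  qual_tier <- character(0)
  for (tip in intruders) {
    nd <- match(tip, tree$tip.label)
    repeat {
      nd <- parent_of[[as.character(nd)]]
      in_clade <- tree$tip.label[tips[[nd]]]
      if (any(focal %in% in_clade)) break
    }
    s <- node_support(nd)
    tier <- lineage_map[[tip]]
    if (!is.na(s) && s >= support_min) {
      qual_support <- c(qual_support, s)
      qual_tier <- c(qual_tier, tier)
    }
  }
  if (length(qual_support)) {
    deepest <- qual_tier[which.max(.TIER_DEPTH[qual_tier])]
    depth <- if (deepest %in% c("LT", "outgroup")) "before_LT"
    else paste0("before_", deepest)
    return(out("SGV", depth, max(qual_support), FALSE))
  }
  out("unresolved", "n/a",
      if (length(intruders)) NA_real_ else node_support(mrca), FALSE)
}

#' Two-tailed Mann-Whitney comparison of max dXY by origin class
#'
#' Exact enumeration of the rank-sum distribution when both classes have at
#' most 8 members; otherwise the tie-corrected normal approximation.
#'
#' @param calls data.frame with columns `origin` and `max_dxy` (e.g. the
#'   per-gene table assembled by the pipeline).
#' @return list: p-value, U statistic, per-class medians and sizes, method.
#' @export
compare_dxy_by_origin <- function(calls) {
  x <- calls$max_dxy[calls$origin == "SGV"]
  y <- calls$max_dxy[calls$origin == "new_mutation"]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  res <- list(p = NA_real_, U = NA_real_,
              median_sgv = if (length(x)) median(x) else NA_real_,
              median_new = if (length(y)) median(y) else NA_real_,
              n_sgv = length(x), n_new = length(y), method = "undefined")
  if (!length(x) || !length(y)) return(res)
  mw <- mann_whitney_test(x, y)
  res[names(mw)] <- mw
  res
}

#' Two-tailed Mann-Whitney rank-sum test
#'
#' @param x,y numeric samples.
#' @return list(p, U, method); U is the number of (x, y) pairs with x > y
#'   (+ half the ties).
#' @export
mann_whitney_test <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n <= 8 && m <= 8) {
    dev <- abs(U - mu)
    sets <- combn(n + m, n)
    Us <- colSums(matrix(r[sets], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(Us - mu) >= dev - 1e-12)
    return(list(p = p, U = U, method = "exact"))
  }
  N <- n + m
  ties <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(p = 1, U = U, method = "normal"))
  z <- (U - mu) / sqrt(sigma2)
  list(p = min(1, 2 * pnorm(-abs(z))), U = U, method = "normal")
}
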