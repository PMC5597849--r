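#' Cluster marker genes into metagenomic linkage groups
#'
#' Deterministic greedy medoid clustering on Spearman correlation across
#' all samples: repeatedly (a) seed with the unclustered gene of highest
#' mean abundance, (b) gather unclustered genes correlating with the
#' seed at `rho >= rho_min`, (c) recompute the medoid (the member
#' maximizing summed within-cluster correlation) and re-gather until
#' stable (at most `max_iter` iterations, ties broken by gene id),
#' (d) accept the cluster if it has at least `min_size` members.
#' Constant gene profiles (undefined correlation) never co-cluster and
#' are warned about.
#'
#' @param abund Marker-gene x sample abundance matrix (>= 8 samples).
#' @param rho_min Minimum Spearman correlation with the medoid, in (0, 1].
#' @param min_size Minimum cluster size.
#' @param max_iter Medoid refinement iterations.
#' @return A named list of MLGs, each `list(mlg_id, members, medoid,
#'   size)`; unclustered gene ids in `attr(, "unclustered")`.
#' @export
cluster_mlgs <- function(abund, rho_min = 0.7, min_size = 5L, max_iter = 20L) {
  if (!(rho_min > 0 && rho_min <= 1)) stop("rho_min must be in (0, 1]")
  if (ncol(abund) < 8L) stop("need at least 8 samples for co-abundance clustering")
  g <- rownames(abund)
  G <- length(g)
  mlgs <- list()
  if (G < min_size) {
    attr(mlgs, "unclustered") <- g
    return(mlgs)
  }
  R <- suppressWarnings(cor(t(.row_ranks(abund))))
  if (anyNA(R)) {
    warning("constant gene profiles have undefined correlation; treated as 0")
    R[is.na(R)] <- 0
  }
  mean_ab <- rowMeans(abund)
  unclustered <- rep(TRUE, G)
  seedable <- rep(TRUE, G)
  while (any(seedable & unclustered)) {
    cand <- which(seedable & unclustered)
    s <- cand[order(-mean_ab[cand], g[cand])][1L]
    members <- which(unclustered & R[s, ] >= rho_min)
    medoid <- s
    for (it in seq_len(max_iter)) {
      if (!length(members)) break
      ssum <- colSums(R[members, members, drop = FALSE])
      med <- members[order(-ssum, g[members])][1L]
      new_members <- which(unclustered & R[med, ] >= rho_min)
      stable <- med == medoid && identical(new_members, members)
      medoid <- med
      members <- new_members
      if (stable) break
    }
    if (length(members) >= min_size) {
      id <- sprintf("MLG%03d", length(mlgs) + 1L)
      mlgs[[id]] <- list(mlg_id = id, members = g[members], medoid = g[medoid],
                         size = length(members))
      unclustered[members] <- FALSE
    } else {
      seedable[s] <- FALSE
    }
  }
  attr(mlgs, "unclustered") <- g[unclustered]
  mlgs
}

#' Robust per-sample abundance of an MLG
#'
#' Interquartile mean (25%-trimmed mean) of the member-gene abundances in
#' each sample, scaled by the member count -- a robust estimate of the
#' summed abundance of the gene set that damps outlier genes.
#'
#' @param mlg An MLG from [cluster_mlgs()], or a character vector of
#'   member gene ids.
#' @param abund Gene-level abundance matrix containing the members.
#' @return A named per-sample numeric vector.
#' @export
mlg_abundance <- function(mlg, abund) {
  members <- if (is.list(mlg)) mlg$members else mlg
  if (!length(members)) stop("empty member list")
  miss <- setdiff(members, rownames(abund))
  if (length(miss)) stop("members missing from abundance matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  sub <- abund[members, , drop = FALSE]
  apply(sub, 2L, function(x) mean(x, trim = 0.25) * length(x))
}

#' Abundance matrix for a list of MLGs
#'
#' @param mlgs List from [cluster_mlgs()].
#' @param abund Gene-level abundance matrix.
#' @return An MLG x sample matrix.
#' @export
mlg_abundance_matrix <- function(mlgs, abund) {
  if (!length(mlgs)) stop("no MLGs")
  t(vapply(mlgs, mlg_abundance, numeric(ncol(abund)), abund = abund))
}

#' Rule-based taxonomy call for an MLG
#'
#' Species call iff >= 90% of member genes hit one species' genome at
#' DNA identity >= 95% and coverage >= 70% of the gene; otherwise genus
#' call iff >= 80% of member genes hit genomes of one genus at >= 85%
#' identity in both DNA and protein; otherwise unclassified. The
#' supporting gene fraction is always reported.
#'
#' @param mlg An MLG (or character vector of member gene ids).
#' @param catalog A `"gene_catalog"` with annotations.
#' @return `list(rank, taxon, fraction)`; `rank` is `"species"`,
#'   `"genus"` or `"unclassified"`.
#' @export
assign_mlg_taxonomy <- function(mlg, catalog) {
  members <- if (is.list(mlg)) mlg$members else mlg
  size <- length(members)
  if (!size) stop("empty member list")
  ann <- catalog$annotations[catalog$annotations$gene_id %in% members, ]

  frac_for <- function(ok, tax_col) {
    hit <- ann[ok, c("gene_id", tax_col)]
    if (!nrow(hit)) return(list(best = 0, taxon = NA_character_))
    per_tax <- tapply(hit$gene_id, hit[[tax_col]],
                      function(gs) length(unique(gs)) / size)
    per_tax <- per_tax[order(-unlist(per_tax), names(per_tax))]
    list(best = per_tax[[1L]], taxon = names(per_tax)[1L])
  }

  sp <- frac_for(ann$dna_identity >= 95 & ann$coverage >= 0.70, "taxon_id")
  if (!is.na(sp$taxon[1L]) && sp$best >= 0.9) {
    return(list(rank = "species", taxon = sp$taxon, fraction = sp$best))
  }
  ge <- frac_for(ann$dna_identity >= 85 & ann$protein_identity >= 85, "genus")
  if (!is.na(ge$taxon[1L]) && ge$best >= 0.8) {
    return(list(rank = "genus", taxon = ge$taxon, fraction = ge$best))
  }
  best <- max(if (is.na(sp$taxon[1L])) 0 else sp$best,
              if (is.na(ge$taxon[1L])) 0 else ge$best)
  list(rank = "unclassified", taxon = NA_character_, fraction = best)
}

#' Enrichment direction of an MLG
#'
#' Two-tailed Mann-Whitney U test on the MLG abundance profile; the
#' direction is the group with the higher median when `p < alpha`,
#' otherwise `"none"`.
#'
#' @param mlg_abund Named per-sample MLG abundance vector.
#' @param cohort Cohort table.
#' @param alpha Significance cut for calling a direction.
#' @return `list(direction, p)`.
#' @export
mlg_enrichment <- function(mlg_abund, cohort, alpha = 0.05) {
  grp <- cohort$group[match(names(mlg_abund), cohort$sample_id)]
  if (anyNA(grp)) stop("samples missing from cohort")
  ca <- mlg_abund[grp == "case"]
  co <- mlg_abund[grp == "control"]
  p <- mannwhitney_test(ca, co)
  dir <- "none"
  if (p < alpha) {
    if (median(ca) > median(co)) dir <- "case-enriched"
    else if (median(ca) < median(co)) dir <- "control-enriched"
  }
  list(direction = dir, p = p)
}

#' Build, profile, classify and orient MLGs in one call
#'
#' Convenience wrapper: cluster the marker genes, compute MLG abundance
#' profiles, assign taxonomy from the catalogue, and call enrichment
#' directions.
#'
#' @param marker_abund Marker-gene x sample abundance matrix.
#' @param catalog A `"gene_catalog"`.
#' @param cohort Cohort table.
#' @param rho_min,min_size See [cluster_mlgs()].
#' @param alpha Direction significance cut (see [mlg_enrichment()]).
#' @return `list(table, abundance, mlgs)`: a summary data.frame
#'   (mlg_id, size, rank, taxon, fraction, direction, p), the MLG x
#'   sample abundance matrix, and the raw MLG list.
#' @export
build_mlgs <- function(marker_abund, catalog, cohort, rho_min = 0.7,
                       min_size = 5L, alpha = 0.05) {
  mlgs <- cluster_mlgs(marker_abund, rho_min = rho_min, min_size = min_size)
  if (!length(mlgs)) {
    return(list(table = data.frame(), abundance = NULL, mlgs = mlgs))
  }
  ab <- mlg_abundance_matrix(mlgs, marker_abund)
  rows <- lapply(mlgs, function(m) {
    tax <- assign_mlg_taxonomy(m, catalog)
    enr <- mlg_enrichment(ab[m$mlg_id, ], cohort, alpha = alpha)
    data.frame(mlg_id = m$mlg_id, size = m$size, rank = tax$rank,
               taxon = if (is.na(tax$taxon[1L])) NA_character_ else tax$taxon,
               fraction = tax$fraction, direction = enr$direction, p = enr$p,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       abundance = ab, mlgs = mlgs)
}
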