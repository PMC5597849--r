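#' Gene relative-abundance profile
#'
#' Length-normalizes unique-read counts and scales each sample to sum 1:
#' `a_gs = (r_gs / L_g) / sum_g'(r_g's / L_g')`. This is the
#' sum-normalized reading of "reads divided by gene length and by total
#' uniquely mapped reads"; set `renormalize = FALSE` for the literal
#' variant `r_gs / (L_g * R_s)` with `R_s` the sample's total uniquely
#' mapped reads (columns then do not sum to 1).
#'
#' @param counts Genes x samples non-negative count matrix.
#' @param catalog A `"gene_catalog"` supplying gene lengths.
#' @param renormalize Scale each column to sum 1 (default).
#' @return A genes x samples abundance matrix; all-zero sample columns
#'   stay all-zero and are reported with a message.
#' @export
gene_relative_abundance <- function(counts, catalog, renormalize = TRUE) {
  len <- setNames(catalog$genes$length_bp, catalog$genes$gene_id)
  miss <- setdiff(rownames(counts), names(len))
  if (length(miss)) {
    stop("genes missing from catalog: ", paste(utils::head(miss, 5L), collapse = ", "))
  }
  L <- len[rownames(counts)]
  if (any(L <= 0)) stop("non-positive gene length for: ",
                        paste(utils::head(rownames(counts)[L <= 0], 5L), collapse = ", "))
  x <- counts / L
  tot <- if (renormalize) colSums(x) else colSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    message("all-zero sample columns left as zero: ",
            paste(colnames(counts)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(x, 2L, tot, "/")
}

.rank_thresholds <- c(species = 95, genus = 85, phylum = 65)

# best annotation per gene: highest DNA identity, ties broken by higher
# coverage then lexicographic taxon id
.best_hits <- function(catalog) {
  ann <- catalog$annotations
  o <- order(ann$gene_id, -ann$dna_identity, -ann$coverage, ann$taxon_id)
  ann <- ann[o, ]
  ann[!duplicated(ann$gene_id), ]
}

#' Aggregate a gene profile to a taxonomic rank
#'
#' A gene contributes to the taxon of its best DNA-identity hit provided
#' the hit covers >= 70% of the gene and the identity reaches the rank
#' threshold (species 95%, genus 85%, phylum 65%); all other genes pool
#' into `"unclassified"`. Taxon abundance is the sum of member gene
#' abundances, so columns that summed to 1 still do.
#'
#' @param abund Gene-level abundance matrix.
#' @param catalog A `"gene_catalog"`.
#' @param rank `"species"`, `"genus"` or `"phylum"`.
#' @return A taxa x samples abundance matrix.
#' @export
taxon_profile <- function(abund, catalog, rank = c("species", "genus", "phylum")) {
  rank <- match.arg(rank)
  thr <- .rank_thresholds[[rank]]
  best <- .best_hits(catalog)
  tax_col <- c(species = "taxon_id", genus = "genus", phylum = "phylum")[[rank]]
  lab <- ifelse(best$coverage >= 0.70 & best$dna_identity >= thr,
                best[[tax_col]], "unclassified")
  assign <- setNames(lab, best$gene_id)
  grp <- assign[rownames(abund)]
  grp[is.na(grp)] <- "unclassified"
  rowsum(abund, grp)
}

#' Aggregate a gene profile to functional features
#'
#' Feature abundance is the sum of member gene abundances at the KO,
#' module or pathway level; genes without an assignment pool into
#' `"unannotated"`.
#'
#' @param abund Gene-level abundance matrix.
#' @param catalog A `"gene_catalog"` with ko/module/pathway columns.
#' @param level `"KO"`, `"module"` or `"pathway"`.
#' @return A features x samples abundance matrix.
#' @export
functional_profile <- function(abund, catalog, level = c("KO", "module", "pathway")) {
  level <- match.arg(level)
  col <- c(KO = "ko_id", module = "module_id", pathway = "pathway_id")[[level]]
  g <- catalog$genes
  assign <- setNames(g[[col]], g$gene_id)
  grp <- assign[rownames(abund)]
  grp[is.na(grp)] <- "unannotated"
  rowsum(abund, grp)
}

#' Rarefied gene count (richness)
#'
#' For each sample, subsamples `depth` reads without replacement from the
#' sample's gene-labelled reads, counts genes with at least one read, and
#' averages over `draws` random drawings. Samples whose total mapped
#' reads fall below `depth` are reported as `NA` with a warning.
#'
#' @param counts Genes x samples count matrix.
#' @param depth Rarefaction depth in reads.
#' @param draws Number of random drawings (the conventional default is 30).
#' @param seed Seed for the drawings.
#' @return A named per-sample numeric vector.
#' @export
rarefied_gene_count <- function(counts, depth, draws = 30L, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  if (draws < 1) stop("draws must be >= 1")
  set.seed(seed)
  totals <- colSums(counts)
  out <- setNames(rep(NA_real_, ncol(counts)), colnames(counts))
  low <- totals < depth
  if (any(low)) {
    warning("samples below rarefaction depth reported as NA: ",
            paste(colnames(counts)[low], collapse = ", "))
  }
  for (s in which(!low)) {
    r <- counts[, s]
    r <- r[r > 0]
    N <- totals[s]
    if (N == depth) { out[s] <- length(r); next }
    cum <- cumsum(r)
    hits <- vapply(seq_len(draws), function(i) {
      idx <- sample.int(N, depth)
      length(unique(findInterval(idx - 1, cum) + 1L))
    }, numeric(1))
    out[s] <- mean(hits)
  }
  out
}

#' Shannon diversity index per sample
#'
#' `H_s = -sum_g a_gs * ln(a_gs)` with zero-abundance terms contributing
#' 0. Columns are normalized defensively; all-zero columns give `NA`.
#'
#' @param abund Features x samples abundance matrix (non-negative).
#' @return A named per-sample numeric vector (natural-log units).
#' @export
shannon_index <- function(abund) {
  if (any(abund < 0)) stop("negative abundances")
  tot <- colSums(abund)
  out <- setNames(rep(NA_real_, ncol(abund)), colnames(abund))
  for (s in which(tot > 0)) {
    p <- abund[, s] / tot[s]
    p <- p[p > 0]
    out[s] <- -sum(p * log(p))
  }
  if (any(tot == 0)) message("all-zero samples excluded from Shannon index")
  out
}

#' Per-feature two-group abundance comparison
#'
#' Mann-Whitney U test per feature between case and control samples with
#' Benjamini-Hochberg correction across the tested features. Features
#' whose mean relative abundance over all samples falls below
#' `min_mean_abund` are excluded before testing (display conventions in
#' this literature use 0.05% for genus panels and 0.001% for
#' MLG/species-phenotype panels).
#'
#' @param abund Features x samples abundance matrix.
#' @param cohort Cohort table with `sample_id` and `group`.
#' @param min_mean_abund Mean-abundance filter applied before testing.
#' @return A data.frame (feature, mean_case, mean_control, median_case,
#'   median_control, p, q, direction) sorted by q then p.
#' @export
compare_groups <- function(abund, cohort, min_mean_abund = 0) {
  grp <- .match_groups(abund, cohort)
  if (min(table(grp)) < 2L) stop("need at least 2 samples per group")
  keep <- rowMeans(abund) >= min_mean_abund
  abund <- abund[keep, , drop = FALSE]
  if (!nrow(abund)) {
    return(data.frame(feature = character(0), mean_case = numeric(0),
                      mean_control = numeric(0), median_case = numeric(0),
                      median_control = numeric(0), p = numeric(0),
                      q = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  is_case <- grp == "case"
  p <- apply(abund, 1L, function(x) mannwhitney_test(x[is_case], x[!is_case]))
  med_ca <- apply(abund[, is_case, drop = FALSE], 1L, median)
  med_co <- apply(abund[, !is_case, drop = FALSE], 1L, median)
  res <- data.frame(
    feature = rownames(abund),
    mean_case = rowMeans(abund[, is_case, drop = FALSE]),
    mean_control = rowMeans(abund[, !is_case, drop = FALSE]),
    median_case = med_ca, median_control = med_co,
    p = p, q = bh_fdr(p),
    direction = ifelse(med_ca > med_co, "case-enriched",
                       ifelse(med_ca < med_co, "control-enriched", "none")),
    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$q, res$p, res$feature), ]
}
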