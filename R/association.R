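#' Spearman rank correlation with p-value
#'
#' Average-rank Spearman correlation. The two-sided p-value is exact
#' (full permutation enumeration, valid under ties) for n <= 10 and uses
#' the t approximation above. Missing pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @return `list(rho, p)`; both `NA` when fewer than 3 complete pairs or
#'   a vector is constant.
#' @export
spearman_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rx, ry)
  p <- if (n <= 10L) {
    .spearman_perm_p(rx, ry)
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    min(1, 2 * pt(-abs(tt), n - 2))
  }
  list(rho = rho, p = p)
}

#' Spearman co-occurrence network over MLG abundances
#'
#' All unordered MLG pairs whose Spearman correlation across all pooled
#' samples exceeds the cut in absolute value (strict inequality).
#' Constant profiles have undefined correlation; their pairs are skipped
#' with a warning.
#'
#' @param mlg_abund MLG x sample abundance matrix (>= 3 samples).
#' @param rho_cut Absolute-correlation edge threshold (the field
#'   convention is 0.4).
#' @return A data.frame of edges (mlg_a, mlg_b, rho, sign) in canonical
#'   `a < b` order.
#' @export
mlg_network <- function(mlg_abund, rho_cut = 0.4) {
  if (ncol(mlg_abund) < 3L) stop("need at least 3 samples")
  ids <- rownames(mlg_abund)
  R <- suppressWarnings(cor(t(.row_ranks(mlg_abund))))
  if (anyNA(R)) {
    warning("constant MLG profiles have undefined correlation; pairs skipped")
  }
  idx <- which(upper.tri(R) & !is.na(R) & abs(R) > rho_cut, arr.ind = TRUE)
  edges <- data.frame(
    mlg_a = ids[idx[, 1L]], mlg_b = ids[idx[, 2L]],
    rho = R[idx],
    sign = ifelse(R[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  edges[order(edges$mlg_a, edges$mlg_b), , drop = FALSE]
}

#' Export a network edge list as GraphML
#'
#' @param edges Edge data.frame from [mlg_network()].
#' @param path Output `.graphml` path.
#' @return The path, invisibly.
#' @export
write_network_graphml <- function(edges, path) {
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' Gross abundance ratio of case- to control-enriched MLGs
#'
#' Per sample, the summed abundance of case-enriched MLGs divided by the
#' summed abundance of control-enriched MLGs -- the community-level
#' dysbiosis index whose correlation with blood glucose is the key
#' phenotype link. Samples with a zero denominator give `NA` with a
#' message.
#'
#' @param mlg_abund MLG x sample abundance matrix.
#' @param directions Named character vector (or data.frame with mlg_id
#'   and direction) assigning `"case-enriched"` / `"control-enriched"`.
#' @return A named per-sample numeric vector.
#' @export
gross_abundance_ratio <- function(mlg_abund, directions) {
  if (is.data.frame(directions)) {
    directions <- setNames(directions$direction, directions$mlg_id)
  }
  directions <- directions[intersect(names(directions), rownames(mlg_abund))]
  up <- names(directions)[directions == "case-enriched"]
  dn <- names(directions)[directions == "control-enriched"]
  if (!length(up) || !length(dn)) {
    stop("need at least one MLG in each enrichment direction")
  }
  num <- colSums(mlg_abund[up, , drop = FALSE])
  den <- colSums(mlg_abund[dn, , drop = FALSE])
  zero <- den == 0
  if (any(zero)) {
    message("zero control-enriched gross abundance; ratio NA for: ",
            paste(colnames(mlg_abund)[zero], collapse = ", "))
    den[zero] <- NA_real_
  }
  num / den
}

#' Per-feature correlations with phenotypes
#'
#' Spearman correlation and two-sided p-value of each feature's abundance
#' against each phenotype column over all samples, with significance
#' marks `'+'` (p < 0.05) and `'++'` (p < 0.01). Rows are filtered to
#' features with mean abundance >= `min_mean_abund` and at least one
#' phenotype at p < 0.05.
#'
#' @param abund Features x samples abundance matrix.
#' @param cohort Cohort table.
#' @param phenotypes Cohort columns to correlate against.
#' @param min_mean_abund Mean-abundance display filter.
#' @return A long data.frame (feature, phenotype, rho, p, mark).
#' @export
feature_phenotype_correlation <- function(abund, cohort,
                                          phenotypes = c("glucose_0", "glucose_60",
                                                         "glucose_120"),
                                          min_mean_abund = 1e-5) {
  idx <- match(colnames(abund), cohort$sample_id)
  if (anyNA(idx)) stop("samples missing from cohort")
  keep_ph <- phenotypes[vapply(phenotypes, function(ph) {
    v <- cohort[[ph]][idx]
    ok <- !is.null(v) && any(is.finite(v))
    if (!ok) warning("phenotype skipped (missing): ", ph)
    ok
  }, logical(1))]
  feats <- rownames(abund)[rowMeans(abund) >= min_mean_abund]
  rows <- list()
  for (f in feats) {
    for (ph in keep_ph) {
      st <- spearman_test(abund[f, ], cohort[[ph]][idx])
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, phenotype = ph, rho = st$rho, p = st$p,
        mark = if (is.na(st$p)) "" else if (st$p < 0.01) "++"
               else if (st$p < 0.05) "+" else "",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(feature = character(0), phenotype = character(0),
               rho = numeric(0), p = numeric(0), mark = character(0),
               stringsAsFactors = FALSE)
  }
  sig <- unique(out$feature[!is.na(out$p) & out$p < 0.05])
  out <- out[out$feature %in% sig, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(s, t) = sum_g |a_gs - a_gt| / sum_g (a_gs + a_gt)`; symmetric,
#' zero diagonal, values in \[0, 1\].
#'
#' @param abund Features x samples non-negative abundance matrix.
#' @return A sample x sample distance matrix.
#' @export
bray_curtis <- function(abund) {
  if (any(abund < 0)) stop("negative abundances")
  zero <- colSums(abund) == 0
  if (sum(zero) >= 2L) {
    stop("distance undefined between all-zero samples: ",
         paste(colnames(abund)[zero], collapse = ", "))
  }
  n <- ncol(abund)
  D <- matrix(0, n, n, dimnames = list(colnames(abund), colnames(abund)))
  for (i in seq_len(n - 1L)) {
    xi <- abund[, i]
    for (j in seq.int(i + 1L, n)) {
      xj <- abund[, j]
      D[i, j] <- D[j, i] <- sum(abs(xi - xj)) / sum(xi + xj)
    }
  }
  D
}

# Anderson's pseudo-F from a distance matrix and group labels
.permanova_f <- function(D2, grp) {
  n <- length(grp)
  a <- length(unique(grp))
  sst <- sum(D2[upper.tri(D2)]) / n
  ssw <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1L) {
      sub <- D2[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' PERMANOVA of group differences in a distance matrix
#'
#' Permutational multivariate analysis of variance: Anderson's pseudo-F
#' from among/within sums of squared distances, with a permutation
#' p-value `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` over seeded raw
#' label permutations (no strata).
#'
#' @param dist Sample x sample distance matrix (e.g. [bray_curtis()]).
#' @param cohort Cohort table, or a vector of group labels in sample
#'   order.
#' @param n_perm Number of permutations (the field convention is 10 000).
#' @param seed Permutation seed.
#' @return `list(pseudo_f, p, n_perm)`.
#' @export
permanova <- function(dist, cohort, n_perm = 10000L, seed = 1L) {
  D <- as.matrix(dist)
  grp <- if (is.data.frame(cohort)) {
    cohort$group[match(rownames(D), cohort$sample_id)]
  } else cohort
  if (anyNA(grp)) stop("samples missing from cohort")
  if (length(unique(grp)) < 2L || min(table(grp)) < 2L) {
    stop("need at least 2 groups with 2 samples per group")
  }
  D2 <- D^2
  fobs <- .permanova_f(D2, grp)
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    if (.permanova_f(D2, sample(grp)) >= fobs - 1e-12) cnt <- cnt + 1L
  }
  list(pseudo_f = fobs, p = (1 + cnt) / (1 + n_perm), n_perm = n_perm)
}

#' Distance-based redundancy analysis on the group factor
#'
#' Principal-coordinate embedding of the distance matrix followed by
#' redundancy analysis constrained on the case/control indicator (via
#' `vegan::capscale`). Negative eigenvalues are discarded by the
#' embedding with a logged note. Feature loadings, when a feature matrix
#' is supplied, are Pearson correlations of feature abundances with the
#' constrained sample scores.
#'
#' @param dist Sample x sample distance matrix from [bray_curtis()].
#' @param cohort Cohort table.
#' @param features Optional features x samples abundance matrix for
#'   loadings.
#' @return `list(scores, var_explained, loadings, ordination)`: sample
#'   scores on the first two axes (constrained axis first), the percent
#'   variance of those axes, per-feature loadings (or `NULL`), and the
#'   underlying `capscale` fit.
#' @export
dbrda <- function(dist, cohort, features = NULL) {
  D <- as.matrix(dist)
  grp <- .match_groups(t(D), cohort)  # columns of t(D) are the samples
  d <- stats::as.dist(D)
  fit <- tryCatch(vegan::capscale(d ~ grp),
                  error = function(e) stop("rank-deficient embedding: ",
                                           conditionMessage(e)))
  eig_all <- c(fit$CCA$eig, fit$CA$eig)
  if (!is.null(fit$CA$imaginary.chi) && fit$CA$imaginary.chi != 0) {
    message("negative eigenvalues discarded from the embedding")
  }
  sc <- vegan::scores(fit, display = "sites", choices = 1:2)
  var2 <- 100 * eig_all[1:2] / sum(eig_all)
  loadings <- NULL
  if (!is.null(features)) {
    feat <- features[, rownames(sc), drop = FALSE]
    loadings <- apply(feat, 1L, function(v) cor(v, sc[, 1L]))
  }
  list(scores = sc, var_explained = var2, loadings = loadings, ordination = fit)
}
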