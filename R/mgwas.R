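#' Adjust abundance profiles for population stratification
#'
#' Abundance-based analogue of EIGENSTRAT: each gene row is standardized
#' (centered; scaled by its sd, zero-sd rows left centered), the sample x
#' sample covariance of the standardized matrix is eigendecomposed, and
#' each gene row is replaced by its residual after projecting out the top
#' `k_axes` eigenvectors. Output rows are orthogonal to the removed axes.
#'
#' @param abund Genes x samples abundance matrix.
#' @param k_axes Number of eigenvector axes to remove; 0 returns the
#'   standardized matrix unchanged.
#' @return The adjusted matrix (continuous; may contain negatives), with
#'   the removed eigenvectors in `attr(, "axes")`.
#' @export
stratification_adjust <- function(abund, k_axes = 2L) {
  n <- ncol(abund)
  if (k_axes >= n) stop("k_axes must be smaller than the number of samples")
  if (k_axes < 0) stop("k_axes must be >= 0")
  mu <- rowMeans(abund)
  sdv <- apply(abund, 1L, sd)
  Xs <- abund - mu
  nz <- sdv > 0
  Xs[nz, ] <- Xs[nz, , drop = FALSE] / sdv[nz]
  if (k_axes == 0L) return(Xs)
  V <- eigen(cov(Xs), symmetric = TRUE)$vectors[, seq_len(k_axes), drop = FALSE]
  out <- Xs - (Xs %*% V) %*% t(V)
  attr(out, "axes") <- V
  out
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact null distribution by enumeration of all group assignments when
#' `n1 + n2 <= 12` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. Complete
#' ties give p = 1.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' mannwhitney_test(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
mannwhitney_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  v <- c(x, y)
  r <- rank(v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(v) > 0L
  n <- n1 + n2
  if (n <= 12L && !ties) {
    cmb <- combn(n, n1)
    Us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
    return(min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- if (U == mu) 0 else (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: `q_i = min over {j : p_j >= p_i} of m * p_j /
#' rank_j`, capped at 1 and order-preserving in p.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  o <- order(p)
  ro <- p[o] * m / seq_len(m)
  q <- numeric(m)
  q[o] <- pmin(1, rev(cummin(rev(ro))))
  q
}

#' Select marker genes by adjusted Mann-Whitney + FDR
#'
#' The MGWAS core: adjust for stratification, run a two-tailed
#' Mann-Whitney U test per gene on the adjusted profiles, correct by
#' Benjamini-Hochberg, and keep genes with `q < q_threshold`. The
#' enrichment direction is reported from the unadjusted group means for
#' interpretability. Genes whose adjusted row has zero variance are
#' skipped, not tested.
#'
#' @param abund Genes x samples relative-abundance matrix.
#' @param cohort Cohort table with `sample_id` and `group`.
#' @param k_axes Stratification axes to remove (see
#'   [stratification_adjust()]).
#' @param q_threshold FDR threshold for marker selection.
#' @return A data.frame (gene_id, p, q, direction, effect = difference
#'   of unadjusted group means) of selected markers, with attributes
#'   `n_tested`, `n_skipped`, and `full` (the complete per-gene table).
#' @export
select_markers <- function(abund, cohort, k_axes = 2L, q_threshold = 0.05) {
  grp <- .match_groups(abund, cohort)
  adj <- stratification_adjust(abund, k_axes)
  sdv <- apply(adj, 1L, sd)
  skip <- sdv == 0
  if (any(skip)) {
    message(sum(skip), " zero-variance genes skipped")
  }
  test <- adj[!skip, , drop = FALSE]
  is_case <- grp == "case"
  p <- apply(test, 1L, function(v) mannwhitney_test(v[is_case], v[!is_case]))
  q <- bh_fdr(p)
  eff <- rowMeans(abund[!skip, is_case, drop = FALSE]) -
    rowMeans(abund[!skip, !is_case, drop = FALSE])
  full <- data.frame(gene_id = rownames(test), p = p, q = q,
                     direction = ifelse(eff >= 0, "case-enriched", "control-enriched"),
                     effect = eff, row.names = NULL, stringsAsFactors = FALSE)
  markers <- full[full$q < q_threshold, , drop = FALSE]
  markers <- markers[order(markers$q, markers$p, markers$gene_id), ]
  rownames(markers) <- NULL
  attr(markers, "n_tested") <- nrow(full)
  attr(markers, "n_skipped") <- sum(skip)
  attr(markers, "full") <- full
  markers
}
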