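#' Derive a stage seed from a master seed
#'
#' Pure function of `(seed, stage)`: every source of randomness in the
#' pipeline draws its seed through this, so a single master seed makes a
#' whole run reproducible while keeping stages decoupled. The result is a
#' non-negative integer below 2^31.
#'
#' @param seed Integer master seed.
#' @param stage Character stage tag (e.g. `"counts"`, `"cv2.fold3"`).
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1L, "counts")
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, about 0
#' for independent ones. Used to score recovery of planted gene blocks by
#' [cluster_mlgs()].
#'
#' @param a,b Vectors of cluster labels over the same elements.
#' @return A number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  den <- (ai + bj) / 2 - expected
  if (den == 0) return(1)
  (nij - expected) / den
}

# rank each row of a feature x sample matrix (average ranks for ties)
.row_ranks <- function(x) t(apply(x, 1L, rank))

# match cohort group labels to the columns of an abundance matrix
.match_groups <- function(abund, cohort) {
  grp <- cohort$group[match(colnames(abund), cohort$sample_id)]
  if (anyNA(grp)) {
    stop("samples missing from cohort: ",
         paste(utils::head(colnames(abund)[is.na(grp)], 5L), collapse = ", "))
  }
  if (!all(grp %in% c("case", "control"))) {
    stop("unknown group labels: ",
         paste(unique(setdiff(grp, c("case", "control"))), collapse = ", "))
  }
  factor(grp, levels = c("control", "case"))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  .write_tsv(df, path)
}
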