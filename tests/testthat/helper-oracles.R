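# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (enumeration, closed forms, direct definitions) and
# never call the implementation paths they check.

# two-tailed Mann-Whitney p by enumeration of all group assignments
oracle_mw_p <- function(x, y) {
  n1 <- length(x)
  v <- c(x, y)
  r <- rank(v)
  U_of <- function(sel) sum(r[sel]) - n1 * (n1 + 1) / 2
  u <- U_of(seq_len(n1))
  cmb <- combn(length(v), n1)
  us <- apply(cmb, 2, U_of)
  min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
}

# direct evaluation of the BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[j] / r[j]))
  }, numeric(1))
}

# AUC by pairwise concordance counting, ties 0.5
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Anderson pseudo-F, written independently from squared-distance sums
oracle_permanova_f <- function(D, grp) {
  n <- length(grp)
  a <- length(unique(grp))
  ss <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + D[i, j]^2
    s / (2 * length(idx))
  }
  sst <- ss(seq_len(n))
  ssw <- sum(vapply(unique(grp), function(g) ss(which(grp == g)), numeric(1)))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# exact PERMANOVA p at small n by enumerating all label assignments
oracle_permanova_exact_p <- function(D, grp) {
  fobs <- oracle_permanova_f(D, grp)
  n1 <- sum(grp == unique(grp)[1])
  cmb <- combn(length(grp), n1)
  fs <- apply(cmb, 2, function(sel) {
    g <- rep("b", length(grp)); g[sel] <- "a"
    oracle_permanova_f(D, g)
  })
  mean(fs >= fobs - 1e-12)
}

# expected rarefied gene count: hypergeometric inclusion probabilities
oracle_rarefaction_mean <- function(r, d) {
  r <- r[r > 0]
  N <- sum(r)
  sum(1 - exp(lchoose(N - r, d) - lchoose(N, d)))
}

# variance of the rarefied gene count via pairwise inclusion probabilities
oracle_rarefaction_var <- function(r, d) {
  r <- r[r > 0]
  N <- sum(r)
  pin <- 1 - exp(lchoose(N - r, d) - lchoose(N, d))
  v <- sum(pin * (1 - pin))
  for (i in seq_along(r)) {
    for (j in seq_along(r)) {
      if (i == j) next
      pij <- 1 - exp(lchoose(N - r[i], d) - lchoose(N, d)) -
        exp(lchoose(N - r[j], d) - lchoose(N, d)) +
        exp(lchoose(N - r[i] - r[j], d) - lchoose(N, d))
      v <- v + (pij - pin[i] * pin[j])
    }
  }
  v
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

# exact two-sided Spearman permutation p by full enumeration (n <= 7)
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  P <- perms(length(x))
  rhos <- apply(P, 1, function(pp) cor(rx, ry[pp]))
  mean(abs(rhos) >= abs(rho) - 1e-9)
}

# --- fixture builders ----------------------------------------------------

# a minimal gene_catalog from explicit annotation rows
make_catalog <- function(annotations, lengths = NULL, ko = NULL) {
  ids <- unique(annotations$gene_id)
  genes <- data.frame(
    gene_id = ids,
    length_bp = if (is.null(lengths)) rep(1000L, length(ids)) else lengths,
    ko_id = if (is.null(ko)) NA_character_ else ko,
    module_id = NA_character_, pathway_id = NA_character_,
    stringsAsFactors = FALSE)
  structure(list(genes = genes, annotations = annotations,
                 species = unique(annotations[, c("taxon_id", "genus", "phylum")])),
            class = "gene_catalog")
}

ann_row <- function(gene, taxon = "spA", genus = "gA", phylum = "pA",
                    dna = 98, prot = 95, cov = 0.9) {
  data.frame(gene_id = gene, taxon_id = taxon, genus = genus, phylum = phylum,
             dna_identity = dna, protein_identity = prot, coverage = cov,
             stringsAsFactors = FALSE)
}

# planted co-abundant blocks: n_blocks species trajectories, each carried
# by block_size genes (exact multiples -> within-block Spearman rho = 1)
make_block_abund <- function(n_blocks = 3, block_size = 6, n_samples = 12,
                             noise = 0, seed = 1) {
  set.seed(seed)
  traj <- matrix(rlnorm(n_blocks * n_samples, 0, 1), n_blocks, n_samples)
  rows <- list()
  labels <- integer(0)
  for (b in seq_len(n_blocks)) {
    for (g in seq_len(block_size)) {
      base <- traj[b, ] * runif(1, 0.5, 2)
      if (noise > 0) base <- base * exp(rnorm(n_samples, 0, noise))
      rows[[length(rows) + 1L]] <- base
      labels <- c(labels, b)
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("gene%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%02d", seq_len(n_samples))
  attr(m, "block") <- labels
  m
}

make_cohort <- function(groups, samples = sprintf("S%02d", seq_along(groups)),
                        glucose = NULL) {
  data.frame(sample_id = samples, group = groups,
             glucose_0 = if (is.null(glucose)) rnorm(length(groups), 5) else glucose,
             glucose_60 = rnorm(length(groups), 8),
             glucose_120 = rnorm(length(groups), 7),
             pbmi = rnorm(length(groups), 21, 2),
             age = rnorm(length(groups), 29, 3),
             stringsAsFactors = FALSE)
}
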