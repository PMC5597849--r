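test_that("spearman_test matches exact enumeration and the t approximation", {
  for (i in 1:6) {
    set.seed(i)
    n <- sample(4:7, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(spearman_test(x, y)$p, oracle_spearman_p(x, y),
                 tolerance = 1e-12, info = i)
    # ties: exact permutation p still matches full enumeration
    xt <- round(x); yt <- round(y)
    if (sd(rank(xt)) > 0 && sd(rank(yt)) > 0) {
      expect_equal(spearman_test(xt, yt)$p, oracle_spearman_p(xt, yt),
                   tolerance = 1e-12, info = paste("ties", i))
    }
  }
  # rho is always the average-rank correlation
  set.seed(50)
  x <- rnorm(30); y <- x + rnorm(30)
  st <- spearman_test(x, y)
  expect_equal(st$rho, cor(x, y, method = "spearman"))
  # t approximation for n > 10 tracks cor.test
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  expect_equal(st$p, ref, tolerance = 1e-10)
  expect_true(is.na(spearman_test(c(1, 2), c(3, 4))$p))
})

test_that("network edges obey the strict correlation cut", {
  ab <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
              d = c(1, 3, 2, 4))
  colnames(ab) <- paste0("S", 1:4)
  edges <- mlg_network(ab, rho_cut = 0.4)
  key <- paste(edges$mlg_a, edges$mlg_b)
  # identical ranks: rho = 1
  expect_equal(edges$rho[key == "a b"], 1)
  # exact rank reversal: rho = -1, negative sign class
  expect_equal(edges$rho[key == "a c"], -1)
  expect_equal(edges$sign[key == "a c"], "negative")
  # strict inequality at the boundary
  expect_equal(nrow(mlg_network(ab, rho_cut = 1.0)), 0L)
  # invariance under monotone transformation of abundances
  edges2 <- mlg_network(ab^3, rho_cut = 0.4)
  expect_equal(edges, edges2)
  # constant profile pairs are skipped with a warning
  abc <- rbind(ab, e = rep(1, 4))
  expect_warning(edges3 <- mlg_network(abc, 0.4), "constant")
  expect_false("e" %in% c(edges3$mlg_a, edges3$mlg_b))
  expect_error(mlg_network(ab[, 1:2]), "3 samples")
})

test_that("gross abundance ratio is scale-invariant and direction-aware", {
  ab <- rbind(up1 = c(2, 4), up2 = c(1, 1), dn1 = c(3, 5))
  colnames(ab) <- c("S1", "S2")
  dirs <- c(up1 = "case-enriched", up2 = "case-enriched", dn1 = "control-enriched")
  r <- gross_abundance_ratio(ab, dirs)
  expect_equal(unname(r), c(3 / 3, 5 / 5))
  expect_equal(gross_abundance_ratio(ab * 7, dirs), r)
  expect_error(gross_abundance_ratio(ab, dirs[c("up1", "up2")]),
               "each enrichment direction")
  # zero denominator: NA with a message
  ab0 <- ab; ab0["dn1", 2] <- 0
  expect_message(r0 <- gross_abundance_ratio(ab0, dirs), "S2")
  expect_true(is.na(r0[["S2"]]))
})

test_that("feature-phenotype correlations mark significance and filter", {
  set.seed(12)
  n <- 20
  cohort <- make_cohort(rep(c("case", "control"), each = 10),
                        glucose = rnorm(n, 5))
  ab <- rbind(tracker = rank(cohort$glucose_0) / 100,
              noise = runif(n))
  colnames(ab) <- cohort$sample_id
  res <- feature_phenotype_correlation(ab, cohort, min_mean_abund = 0)
  tr <- res[res$feature == "tracker" & res$phenotype == "glucose_0", ]
  expect_equal(tr$rho, 1)
  expect_equal(tr$mark, "++")
  # filter above every mean empties the table
  expect_equal(nrow(feature_phenotype_correlation(ab, cohort,
                                                  min_mean_abund = 10)), 0L)
  # all-missing phenotype is skipped with a warning
  cohort$glucose_120 <- NA_real_
  expect_warning(res2 <- feature_phenotype_correlation(ab, cohort,
                                                       min_mean_abund = 0),
                 "glucose_120")
  expect_false("glucose_120" %in% res2$phenotype)
})

test_that("bray-curtis matches hand values and the vegan oracle", {
  ab <- matrix(c(0.5, 0.5, 1, 0), 2, 2,
               dimnames = list(c("f1", "f2"), c("s1", "s2")))
  D <- bray_curtis(ab)
  expect_equal(D["s1", "s2"], 0.5)
  # identical columns -> 0; disjoint supports -> 1
  dup <- cbind(ab, s3 = ab[, "s1"])
  expect_equal(bray_curtis(dup)["s1", "s3"], 0)
  disj <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(bray_curtis(disj)["s1", "s2"], 1)
  # random matrices against vegan::vegdist
  set.seed(31)
  m <- matrix(abs(rnorm(6 * 9)), 6, 9,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:9)))
  expect_equal(bray_curtis(m),
               as.matrix(vegan::vegdist(t(m), "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  # symmetry and identity of indiscernibles
  D9 <- bray_curtis(m)
  expect_equal(D9, t(D9))
  expect_equal(unname(diag(D9)), rep(0, 9))
  expect_error(bray_curtis(cbind(disj, s3 = c(0, 0), s4 = c(0, 0))), "all-zero")
})

test_that("permanova pseudo-F matches oracles and the p-value bound", {
  set.seed(41)
  m <- matrix(abs(rnorm(5 * 8)), 5, 8,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:8)))
  m <- sweep(m, 2, colSums(m), "/")
  D <- bray_curtis(m)
  grp <- rep(c("case", "control"), each = 4)
  res <- permanova(D, grp, n_perm = 199, seed = 5)
  # pseudo-F equals both the independent definition and vegan::adonis2
  expect_equal(res$pseudo_f, oracle_permanova_f(D, grp), tolerance = 1e-12)
  ad <- vegan::adonis2(stats::as.dist(D) ~ grp, permutations = 19)
  expect_equal(res$pseudo_f, ad$F[1], tolerance = 1e-10)
  # (1 + count) / (1 + n_perm) bound: p is on the exact permutation grid
  expect_true(res$p >= 1 / 200 && res$p <= 1)
  expect_equal(round(res$p * 200), res$p * 200, tolerance = 1e-12)
  # widely separated clouds reach the lower bound (n large enough that a
  # resampled permutation essentially never redraws the exact split)
  sep <- cbind(matrix(c(0.9, 0.1), 2, 10), matrix(c(0.1, 0.9), 2, 10))
  sep <- sep + abs(matrix(rnorm(40, 0, 0.005), 2, 20))
  dimnames(sep) <- list(c("f1", "f2"), paste0("s", 1:20))
  Ds <- bray_curtis(sweep(sep, 2, colSums(sep), "/"))
  rs <- permanova(Ds, rep(c("case", "control"), each = 10), n_perm = 499, seed = 3)
  expect_equal(rs$p, 1 / 500)
  # p from sampled permutations is consistent with exhaustive enumeration
  pex <- oracle_permanova_exact_p(D, grp)
  expect_lt(abs(res$p - pex), 0.12)
  expect_error(permanova(D, rep("case", 8), n_perm = 10), "2 samples")
})

test_that("db-RDA separates planted groups and preserves replicate geometry", {
  set.seed(61)
  n <- 24
  grp <- rep(c("case", "control"), each = n / 2)
  centers <- ifelse(grp == "case", 0.8, 0.2)
  ab <- rbind(f1 = centers + runif(n, 0, 0.05),
              f2 = 1 - centers + runif(n, 0, 0.05),
              f3 = runif(n, 0.1, 0.2))
  ab <- sweep(ab, 2, colSums(ab), "/")
  colnames(ab) <- sprintf("S%02d", 1:n)
  cohort <- make_cohort(grp, samples = colnames(ab))
  D <- bray_curtis(ab)
  ord <- dbrda(D, cohort, features = ab)
  r_pb <- cor(ord$scores[, 1], as.numeric(grp == "case"))
  expect_gt(abs(r_pb), 0.8)
  expect_length(ord$var_explained, 2L)
  expect_true(all(is.finite(ord$var_explained)))
  expect_length(ord$loadings, 3L)
  # randomized labels explain roughly chance variance on the constrained axis
  set.seed(62)
  perm_sep <- replicate(30, {
    cs <- make_cohort(sample(grp), samples = colnames(ab))
    abs(cor(dbrda(D, cs)$scores[, 1], as.numeric(cs$group == "case")))
  })
  obs_rand <- abs(cor(dbrda(D, make_cohort(rep(c("case", "control"), n / 2),
                                           samples = colnames(ab)))$scores[, 1],
                      rep(c(1, 0), n / 2)))
  expect_lt(obs_rand, quantile(perm_sep, 0.95) + 0.2)
  # duplicating every sample preserves the embedding geometry for duplicates
  ab2 <- cbind(ab, ab)
  colnames(ab2) <- c(colnames(ab), sprintf("D%02d", 1:n))
  cohort2 <- rbind(cohort, transform(cohort, sample_id = sprintf("D%02d", 1:n)))
  ord2 <- dbrda(bray_curtis(ab2), cohort2)
  d_orig <- as.matrix(dist(ord2$scores[1:n, ]))
  d_dup <- as.matrix(dist(ord2$scores[(n + 1):(2 * n), ]))
  expect_equal(d_orig, d_dup, tolerance = 1e-6, ignore_attr = TRUE)
})
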