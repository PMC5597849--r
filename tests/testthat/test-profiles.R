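test_that("gene relative abundance implements the length-normalized profile", {
  catal <- make_catalog(rbind(ann_row("g1"), ann_row("g2")),
                        lengths = c(100L, 200L))
  counts <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  ab <- gene_relative_abundance(counts, catal)
  expect_equal(unname(ab[, 1]), c(2 / 3, 1 / 3))

  # single-gene catalogue: abundance is identically 1
  c1 <- make_catalog(ann_row("g1"), lengths = 500L)
  m1 <- matrix(c(3, 17, 1), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_equal(unname(gene_relative_abundance(m1, c1)[1, ]), rep(1, 3))

  # permuting gene order permutes rows identically
  ab_perm <- gene_relative_abundance(counts[c("g2", "g1"), , drop = FALSE], catal)
  expect_equal(ab_perm, ab[c("g2", "g1"), , drop = FALSE])

  # literal (un-renormalized) variant: r / (L * total uniquely mapped reads)
  lit <- gene_relative_abundance(counts, catal, renormalize = FALSE)
  expect_equal(unname(lit[, 1]), c(10 / (100 * 20), 10 / (200 * 20)))

  # errors: unknown gene, zero length
  bad <- matrix(1, 1, 1, dimnames = list("gX", "s1"))
  expect_error(gene_relative_abundance(bad, catal), "gX")
  c0 <- make_catalog(ann_row("g1"), lengths = 0L)
  expect_error(gene_relative_abundance(m1, c0), "length")

  # all-zero sample columns stay zero and are flagged
  z <- matrix(c(5, 3, 0, 0), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_message(abz <- gene_relative_abundance(z, catal), "all-zero")
  expect_equal(unname(abz[, "s2"]), c(0, 0))
})

test_that("taxon assignment honours identity and coverage thresholds", {
  ann <- rbind(
    ann_row("g1", taxon = "spA", genus = "gA", phylum = "pA", dna = 86, cov = 0.75),
    ann_row("g2", taxon = "spB", genus = "gB", phylum = "pB", dna = 99, cov = 0.50),
    ann_row("g3", taxon = "spC", genus = "gC", phylum = "pC", dna = 96, cov = 0.80))
  catal <- make_catalog(ann)
  ab <- matrix(1 / 3, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))

  sp <- taxon_profile(ab, catal, "species")
  ge <- taxon_profile(ab, catal, "genus")
  ph <- taxon_profile(ab, catal, "phylum")
  # 86% identity, coverage ok: genus and phylum but not species
  expect_false("spA" %in% rownames(sp))
  expect_true("gA" %in% rownames(ge))
  expect_true("pA" %in% rownames(ph))
  # coverage 0.5 at 99% identity: unclassified at every rank
  expect_false("spB" %in% rownames(sp))
  expect_false("gB" %in% rownames(ge))
  expect_false("pB" %in% rownames(ph))
  # clean hit: classified everywhere
  expect_true(all(c("spC") %in% rownames(sp)))
  # conservation including the unclassified pool
  for (m in list(sp, ge, ph)) expect_equal(unname(colSums(m)), c(1, 1))
  expect_error(taxon_profile(ab, catal, "order"))

  # all genes in one genus collapse to a profile of 1
  ann1 <- rbind(ann_row("g1", genus = "gX"), ann_row("g2", genus = "gX"))
  ab1 <- matrix(c(0.4, 0.6), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  ge1 <- taxon_profile(ab1, make_catalog(ann1), "genus")
  expect_equal(unname(ge1["gX", 1]), 1)
})

test_that("best-hit selection prefers identity, then coverage, then taxon id", {
  ann <- rbind(
    ann_row("g1", taxon = "spA", dna = 97, cov = 0.8),
    ann_row("g1", taxon = "spB", dna = 99, cov = 0.75),
    ann_row("g2", taxon = "spD", dna = 98, cov = 0.9),
    ann_row("g2", taxon = "spC", dna = 98, cov = 0.9))
  catal <- make_catalog(ann)
  ab <- matrix(0.5, 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  sp <- taxon_profile(ab, catal, "species")
  expect_setequal(rownames(sp), c("spB", "spC"))  # identity wins; ties by id
})

test_that("functional profiles conserve abundance and pool unannotated genes", {
  ann <- rbind(ann_row("g1"), ann_row("g2"), ann_row("g3"))
  catal <- make_catalog(ann, ko = c("K1", "K2", NA))
  ab <- matrix(c(0.5, 0.3, 0.2), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s1"))
  ko <- functional_profile(ab, catal, "KO")
  expect_equal(unname(ko["K1", 1]), 0.5)
  expect_equal(unname(ko["unannotated", 1]), 0.2)
  expect_equal(unname(colSums(ko)), 1)
  # empty KO map: everything pools into a single unannotated feature
  none <- make_catalog(ann, ko = c(NA, NA, NA))
  ko0 <- functional_profile(ab, none, "KO")
  expect_equal(rownames(ko0), "unannotated")
  expect_equal(unname(ko0[1, 1]), 1)
})

test_that("rarefied gene count matches trivial identities and the hypergeometric oracle", {
  r <- c(g1 = 5, g2 = 3, g3 = 0, g4 = 12, g5 = 1, g6 = 7, g7 = 2)
  counts <- matrix(r, ncol = 1, dimnames = list(names(r), "s1"))
  # exhaustive subsample returns the observed richness for any draws
  expect_equal(unname(rarefied_gene_count(counts, sum(r), draws = 3)), 6)
  # a single read hits exactly one gene
  expect_equal(unname(rarefied_gene_count(counts, 1, draws = 10)), 1)
  # closed-form inclusion-probability oracle within 3 MC standard errors
  d <- 10L; draws <- 1500L
  obs <- unname(rarefied_gene_count(counts, d, draws = draws, seed = 99))
  mu <- oracle_rarefaction_mean(r, d)
  se <- sqrt(oracle_rarefaction_var(r, d) / draws)
  expect_lt(abs(obs - mu), 3 * se)
  # monotone non-decreasing in depth in expectation
  lo <- unname(rarefied_gene_count(counts, 5, draws = 300, seed = 1))
  hi <- unname(rarefied_gene_count(counts, 20, draws = 300, seed = 1))
  expect_lte(lo, hi)
  # shallow samples are NA with a warning
  two <- cbind(counts, s2 = c(1, 0, 0, 0, 0, 0, 0))
  expect_warning(out <- rarefied_gene_count(two, 5, draws = 5), "s2")
  expect_true(is.na(out["s2"]))
  expect_error(rarefied_gene_count(counts, 0, 10), "depth")
  expect_error(rarefied_gene_count(counts, 5, 0), "draws")
})

test_that("shannon index matches closed forms and is order/zero invariant", {
  un <- matrix(rep(1 / 7, 7), 7, 1, dimnames = list(paste0("g", 1:7), "s1"))
  expect_equal(unname(shannon_index(un)), log(7))
  one <- matrix(c(1, 0, 0), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(shannon_index(one)), 0)
  p <- matrix(c(0.5, 0.25, 0.25), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(shannon_index(p)), 1.5 * log(2), tolerance = 1e-12)
  # order invariance and zero-padding invariance
  expect_equal(unname(shannon_index(p[c(3, 1, 2), , drop = FALSE])),
               unname(shannon_index(p)))
  padded <- rbind(p, g4 = 0, g5 = 0)
  expect_equal(unname(shannon_index(padded)), unname(shannon_index(p)))
  expect_error(shannon_index(-p), "negative")
})

test_that("group comparison applies the abundance filter and tie conventions", {
  set.seed(8)
  ab <- rbind(
    flat = rep(0.25, 12),
    shifted = c(rep(0.5, 6), rep(0.1, 6)) + runif(12, 0, 1e-3),
    rare = rep(1e-6, 12))
  colnames(ab) <- sprintf("S%02d", 1:12)
  cohort <- make_cohort(rep(c("case", "control"), each = 6))
  res <- compare_groups(ab, cohort, min_mean_abund = 1e-4)
  expect_false("rare" %in% res$feature)         # filtered before testing
  expect_equal(res$p[res$feature == "flat"], 1) # complete ties
  expect_equal(res$direction[res$feature == "shifted"], "case-enriched")
  # filter larger than every mean: empty result, no error
  empty <- compare_groups(ab, cohort, min_mean_abund = 1)
  expect_equal(nrow(empty), 0L)
  expect_error(compare_groups(ab, make_cohort(rep("weird", 12))), "group")
})
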