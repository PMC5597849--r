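test_that("catalogue construction partitions genes into species with valid annotations", {
  cfg <- synthetic_config(n_species = 3, genes_per_species = 10,
                          annotation_noise = 0, seed = 11)
  cat3 <- generate_catalog(cfg)
  expect_equal(nrow(cat3$genes), 30L)
  sp <- attr(cat3, "species_of_gene")
  expect_equal(unname(table(sp)), rep(10L, 3), ignore_attr = TRUE)
  expect_equal(length(unique(sp)), 3L)
  # noiseless: every annotation passes the species assignment rule
  expect_true(all(cat3$annotations$dna_identity >= 95))
  expect_true(all(cat3$annotations$coverage >= 0.70))
  expect_false(anyDuplicated(cat3$genes$gene_id) > 0)
  expect_true(all(cat3$genes$length_bp >= cfg$gene_length_range[1] &
                    cat3$genes$length_bp <= cfg$gene_length_range[2]))
})

test_that("identical config + seed reproduces byte-identical datasets", {
  cfg <- synthetic_config(n_case = 6, n_control = 6, n_species = 4,
                          genes_per_species = 5, depth_mean = 5e3, seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts, d2$counts)
  expect_identical(d1$cohort, d2$cohort)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_dataset(d1, dir1); write_dataset(d2, dir2)
  for (f in c("catalog.tsv", "counts.tsv", "cohort.tsv", "truth.json")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     info = f)
  }
  # a different seed changes the data
  d3 <- simulate_dataset(synthetic_config(n_case = 6, n_control = 6,
                                          n_species = 4, genes_per_species = 5,
                                          depth_mean = 5e3, seed = 43))
  expect_false(identical(d1$counts, d3$counts))
})

test_that("count rates are length-proportional within species and Poisson-centered", {
  cfg <- synthetic_config(n_case = 5, n_control = 5, n_species = 3,
                          genes_per_species = 8, depth_mean = 2e4,
                          annotation_noise = 0, seed = 7)
  catal <- generate_catalog(cfg)
  cc <- generate_counts(catal, cfg)
  rate <- mgwas:::.gene_rate_matrix(catal, cc$truth$species_relabund,
                                    cc$truth$sample_depth)
  # within a species and sample, expected counts are proportional to length
  sp <- attr(catal, "species_of_gene")
  g <- names(sp)[sp == sp[[1]]]
  L <- catal$genes$length_bp[match(g, catal$genes$gene_id)]
  expect_equal(unname(rate[g, 1] / rate[g[1], 1]), L / L[1], tolerance = 1e-12)
  # column totals match the realized per-sample depth
  expect_equal(colSums(rate), cc$truth$sample_depth, tolerance = 1e-9)
  # Poisson mean identity: MC replicate draws around the fixed rate matrix
  set.seed(1)
  reps <- 100L
  g_sel <- rownames(rate)[1:4]
  mc <- replicate(reps, rpois(length(g_sel), rate[g_sel, 1]))
  mc_mean <- rowMeans(mc)
  mc_sd <- sqrt(rate[g_sel, 1] / reps)
  expect_true(all(abs(mc_mean - rate[g_sel, 1]) <= 3 * mc_sd))
  # and the generated dataset's counts are standardized residuals of the rate
  z <- (cc$counts - rate) / sqrt(pmax(rate, 1e-12))
  z <- z[rate > 20]
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_gt(sd(z), 0.85); expect_lt(sd(z), 1.15)
})

test_that("per-sample totals track depth_mean", {
  cfg <- synthetic_config(n_case = 10, n_control = 10, n_species = 10,
                          genes_per_species = 10, depth_mean = 5e4, seed = 3)
  ds <- simulate_dataset(cfg)
  tot <- colSums(ds$counts)
  expect_lt(abs(mean(tot) / cfg$depth_mean - 1), 0.15)
})

test_that("noiseless phenotype is a monotone map of the true ratio", {
  cfg <- synthetic_config(n_case = 10, n_control = 10, n_species = 10,
                          genes_per_species = 5, depth_mean = 1e4,
                          phenotype_noise_sd = 0, seed = 5)
  ds <- simulate_dataset(cfg)
  st <- cor(rank(ds$truth$true_log_ratio), rank(ds$cohort$glucose_0))
  expect_equal(st, 1)
})

test_that("cohort respects the case/control design sizes", {
  cfg <- synthetic_config(n_case = 43, n_control = 81, n_species = 10,
                          genes_per_species = 5, depth_mean = 1e4, seed = 2)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$cohort), 124L)
  expect_equal(sum(ds$cohort$group == "case"), 43L)
  expect_true(all(ds$cohort$glucose_0 > 0))
})

test_that("null effect decouples group labels from species abundances", {
  cfg <- synthetic_config(n_case = 100, n_control = 100, n_species = 20,
                          genes_per_species = 10, depth_mean = 2e4,
                          effect_log2fc = 0, seed = 1)
  ds <- simulate_dataset(cfg)
  grp <- as.numeric(ds$cohort$group == "case")
  r <- apply(ds$truth$species_relabund, 1, cor, y = grp)
  expect_lt(max(abs(r)), 0.15)
  expect_lt(median(abs(r)), 0.06)
})

test_that("degenerate phenotype models signal errors", {
  cfg <- synthetic_config(n_case = 5, n_control = 5, n_species = 4,
                          genes_per_species = 5, depth_mean = 1e4,
                          n_diff_species = 0, seed = 1)
  catal <- generate_catalog(cfg)
  cc <- generate_counts(catal, cfg)
  expect_error(generate_cohort(cfg, cc$truth, cc$counts), "degenerate")
  expect_error(synthetic_config(n_diff_species = 5, n_species = 4),
               "n_diff_species")
})

test_that("dataset round-trips through the TSV interchange files", {
  cfg <- synthetic_config(n_case = 5, n_control = 5, n_species = 4,
                          genes_per_species = 5, depth_mean = 5e3, seed = 13)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  counts <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(counts, ds$counts, ignore_attr = TRUE)
  catal <- read_catalog(file.path(dir, "catalog.tsv"))
  expect_setequal(catal$genes$gene_id, ds$catalog$genes$gene_id)
  cohort <- read_cohort(file.path(dir, "cohort.tsv"))
  expect_equal(cohort$group, ds$cohort$group)
  truth <- read_truth(file.path(dir, "truth.json"))
  expect_setequal(truth$planted_case, ds$truth$planted_case)
})
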