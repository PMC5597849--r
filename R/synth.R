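#' Configuration for the synthetic MGWAS dataset generator
#'
#' Defines the "stated world" that all downstream tests run against:
#' genes organized into latent species, log-normal species abundances,
#' planted case/control effects on a subset of species, an optional
#' rank-one confounder axis aligned with case status, and an OGTT glucose
#' phenotype coupled to the planted effect.
#'
#' @param n_case,n_control Number of case / control samples.
#' @param n_species Number of latent species.
#' @param genes_per_species Genes per species: a single count, or a
#'   length-2 range `c(min, max)` sampled uniformly per species.
#' @param gene_length_range Gene length interval in bp.
#' @param depth_mean Mean per-sample mapped-read depth; realized depths
#'   are log-normal around this with coefficient of variation `depth_cv`.
#' @param n_diff_species Number of differentially abundant species;
#'   directions alternate case-/control-enriched.
#' @param effect_log2fc Planted log2 fold change of differential species
#'   in case samples.
#' @param confounder_strength Loading (on the log-abundance scale) of a
#'   rank-one stratification axis that perturbs a random half of species.
#'   The axis is correlated with case status so that, when active, it
#'   genuinely confounds naive per-gene tests.
#' @param phenotype_noise_sd Gaussian noise sd of the glucose phenotypes
#'   (mmol/L).
#' @param glucose_coupling Multiplier (>= 0) on the coupling between the
#'   true case/control species log-ratio and glucose; 0 decouples the
#'   phenotype entirely.
#' @param annotation_noise Fraction in \[0, 1\] of genes whose catalogue
#'   annotation is replaced by an off-target hit below all identity and
#'   coverage thresholds.
#' @param overdispersion Negative-binomial overdispersion of counts
#'   (0 = Poisson, the default).
#' @param depth_cv Coefficient of variation of per-sample depth.
#' @param seed Integer seed; identical config + seed gives identical data.
#' @return A validated list of class `"synthetic_config"`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_case = 10, n_control = 10, n_species = 5,
#'                         genes_per_species = 8, depth_mean = 2e4)
synthetic_config <- function(n_case = 40L, n_control = 40L,
                             n_species = 40L, genes_per_species = 25L,
                             gene_length_range = c(500L, 1500L),
                             depth_mean = 2e5,
                             n_diff_species = min(6L, n_species),
                             effect_log2fc = 2, confounder_strength = 0,
                             phenotype_noise_sd = 0.4, glucose_coupling = 1,
                             annotation_noise = 0.05, overdispersion = 0,
                             depth_cv = 0.2, seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_species = as.integer(n_species),
              genes_per_species = as.integer(genes_per_species),
              gene_length_range = as.integer(gene_length_range),
              depth_mean = depth_mean, n_diff_species = as.integer(n_diff_species),
              effect_log2fc = effect_log2fc,
              confounder_strength = confounder_strength,
              phenotype_noise_sd = phenotype_noise_sd,
              glucose_coupling = glucose_coupling,
              annotation_noise = annotation_noise,
              overdispersion = overdispersion, depth_cv = depth_cv,
              seed = as.integer(seed))
  stopifnot(cfg$n_case >= 1L, cfg$n_control >= 1L, cfg$n_species >= 1L,
            all(cfg$genes_per_species >= 1L),
            length(cfg$genes_per_species) %in% c(1L, 2L),
            length(cfg$gene_length_range) == 2L,
            all(cfg$gene_length_range >= 1L),
            cfg$depth_mean > 0,
            cfg$n_diff_species >= 0L, cfg$n_diff_species <= cfg$n_species,
            cfg$confounder_strength >= 0, cfg$phenotype_noise_sd >= 0,
            cfg$glucose_coupling >= 0,
            cfg$annotation_noise >= 0, cfg$annotation_noise <= 1,
            cfg$overdispersion >= 0, cfg$depth_cv >= 0)
  structure(cfg, class = "synthetic_config")
}

# baseline OGTT glucose model at the reference effect size (log2fc = 2):
# intercepts near the 5.1 / 10.0 / 8.5 mmol/L diagnostic cuts, slopes on
# the standardized species log-ratio.
.glucose_intercepts <- c(glucose_0 = 4.7, glucose_60 = 7.8, glucose_120 = 6.6)
.glucose_base_slopes <- c(glucose_0 = 0.5, glucose_60 = 0.8, glucose_120 = 0.7)
.reference_effect <- 2

#' Generate a synthetic gene catalogue
#'
#' One annotation row per gene links it to its true species' genome with
#' DNA identity >= 95% and alignment coverage >= 70% (so a noiseless
#' catalogue passes the species assignment rule everywhere); an
#' `annotation_noise` fraction of genes instead receive off-target hits
#' below all thresholds. Species carry genus and phylum labels (two
#' species per genus, eight per phylum); about 80% of genes get a KO,
#' grouped into modules and pathways.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `"gene_catalog"` with elements `genes`
#'   (gene_id, length_bp, ko_id, module_id, pathway_id), `annotations`
#'   (gene_id, taxon_id, genus, phylum, dna_identity, protein_identity,
#'   coverage), and `species` (taxon_id, genus, phylum). The latent
#'   gene-to-species map is carried in `attr(, "species_of_gene")` for
#'   the truth record; pipeline stages only consume the annotations.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "catalog"))
  ns <- config$n_species
  gps <- config$genes_per_species
  per_sp <- if (length(gps) == 2L) {
    sample(seq.int(gps[1L], gps[2L]), ns, replace = TRUE)
  } else rep.int(gps, ns)
  species <- sprintf("sp%03d", seq_len(ns))
  genus <- sprintf("g%03d", ceiling(seq_len(ns) / 2))
  phylum <- sprintf("p%02d", ceiling(seq_len(ns) / 8))
  G <- sum(per_sp)
  gene_id <- sprintf("gene%05d", seq_len(G))
  sp_of_gene <- rep(species, per_sp)
  len <- sample(seq.int(config$gene_length_range[1L], config$gene_length_range[2L]),
                G, replace = TRUE)

  noisy <- runif(G) < config$annotation_noise
  ann <- data.frame(
    gene_id = gene_id,
    taxon_id = sp_of_gene,
    genus = genus[match(sp_of_gene, species)],
    phylum = phylum[match(sp_of_gene, species)],
    dna_identity = runif(G, 95.5, 99.9),
    protein_identity = runif(G, 90, 99.5),
    coverage = runif(G, 0.72, 0.98),
    stringsAsFactors = FALSE)
  if (any(noisy)) {
    # off-target decoy below every threshold (identity < 65, coverage < 0.7)
    k <- sum(noisy)
    decoy <- sample(ns, k, replace = TRUE)
    ann$taxon_id[noisy] <- paste0("decoy_", species[decoy])
    ann$genus[noisy] <- paste0("decoy_", genus[decoy])
    ann$phylum[noisy] <- paste0("decoy_", phylum[decoy])
    ann$dna_identity[noisy] <- runif(k, 40, 60)
    ann$protein_identity[noisy] <- runif(k, 25, 50)
    ann$coverage[noisy] <- runif(k, 0.30, 0.65)
  }

  n_ko <- max(10L, 3L * ns)
  ko_pool <- sprintf("K%05d", seq_len(n_ko))
  has_ko <- runif(G) < 0.8
  ko <- rep(NA_character_, G)
  ko[has_ko] <- sample(ko_pool, sum(has_ko), replace = TRUE)
  ko_idx <- match(ko, ko_pool)
  module <- ifelse(is.na(ko), NA_character_, sprintf("M%04d", ceiling(ko_idx / 5)))
  pathway <- ifelse(is.na(ko), NA_character_, sprintf("path%03d", ceiling(ko_idx / 20)))

  genes <- data.frame(gene_id = gene_id, length_bp = len, ko_id = ko,
                      module_id = module, pathway_id = pathway,
                      stringsAsFactors = FALSE)
  out <- structure(list(genes = genes, annotations = ann,
                        species = data.frame(taxon_id = species, genus = genus,
                                             phylum = phylum,
                                             stringsAsFactors = FALSE)),
                   class = "gene_catalog")
  attr(out, "species_of_gene") <- setNames(sp_of_gene, gene_id)
  out
}

# species relative-abundance model shared by generate_counts() and
# bayes_auc(): log-normal species abundances, planted effect on the
# differential species in planted-case samples, and a rank-one
# confounder axis aligned with case status.
.species_model <- function(config, n, planted_case, diff_sp, diff_dir,
                           conf_species, seed) {
  set.seed(seed)
  ns <- config$n_species
  base <- rnorm(ns, 0, 1.5)
  logA <- matrix(rnorm(ns * n, 0, 0.7), ns, n) + base
  eff <- config$effect_log2fc * log(2)
  if (length(diff_sp)) {
    logA[diff_sp[diff_dir == "case"], planted_case] <-
      logA[diff_sp[diff_dir == "case"], planted_case, drop = FALSE] + eff
    logA[diff_sp[diff_dir == "control"], planted_case] <-
      logA[diff_sp[diff_dir == "control"], planted_case, drop = FALSE] - eff
  }
  case_ind <- rep(-1, n); case_ind[planted_case] <- 1
  z <- (rnorm(n) + case_ind) / sqrt(2)
  if (config$confounder_strength > 0 && length(conf_species)) {
    logA[conf_species, ] <- logA[conf_species, , drop = FALSE] +
      config$confounder_strength * rep(z, each = length(conf_species))
  }
  A <- exp(logA)
  list(relabund = sweep(A, 2L, colSums(A), "/"), confounder_score = z)
}

#' Generate a synthetic read-count matrix with ground truth
#'
#' Per-sample species abundances are log-normal; the differential species
#' are shifted by `2^(+/- effect_log2fc)` in the planted case samples
#' (samples `1..n_case`); a rank-one confounder axis of strength
#' `confounder_strength` perturbs the log-abundances of a random half of
#' species. Each gene's read count is Poisson (or negative binomial if
#' `overdispersion > 0`) around `depth * species relative abundance *
#' the gene's length share within its species`, so per-sample totals are
#' approximately `depth_mean` and expected counts are proportional to
#' gene length at fixed species abundance.
#'
#' @param catalog A catalogue from [generate_catalog()].
#' @param config The matching [synthetic_config()].
#' @return `list(counts, truth)`: `counts` is a genes x samples integer
#'   matrix; `truth` records `species_of_gene`, `differential_species`
#'   (taxon_id, direction), `confounder_score` and the perturbed species,
#'   the planted case samples, realized `sample_depth`, and the true
#'   species relative-abundance matrix.
#' @export
generate_counts <- function(catalog, config) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(config, "synthetic_config"))
  sp_of_gene <- attr(catalog, "species_of_gene")
  species <- catalog$species$taxon_id
  n <- config$n_case + config$n_control
  samples <- sprintf("S%03d", seq_len(n))
  planted_case <- seq_len(config$n_case)

  set.seed(derive_seed(config$seed, "design"))
  nd <- config$n_diff_species
  diff_sp <- if (nd > 0L) sort(sample(config$n_species, nd)) else integer(0)
  diff_dir <- rep(c("case", "control"), length.out = nd)
  conf_species <- sample(config$n_species, floor(config$n_species / 2))

  mod <- .species_model(config, n, planted_case, diff_sp, diff_dir,
                        conf_species, derive_seed(config$seed, "counts"))
  relab <- mod$relabund
  rownames(relab) <- species; colnames(relab) <- samples

  set.seed(derive_seed(config$seed, "sampling"))
  sdlog <- sqrt(log(1 + config$depth_cv^2))
  depth <- rlnorm(n, log(config$depth_mean) - sdlog^2 / 2, sdlog)

  rate <- .gene_rate_matrix(catalog, relab, depth)
  counts <- if (config$overdispersion > 0) {
    matrix(rnbinom(length(rate), size = 1 / config$overdispersion, mu = rate),
           nrow(rate), ncol(rate))
  } else {
    matrix(rpois(length(rate), rate), nrow(rate), ncol(rate))
  }
  dimnames(counts) <- dimnames(rate)

  truth <- list(
    species_of_gene = sp_of_gene,
    differential_species = data.frame(taxon_id = species[diff_sp],
                                      direction = diff_dir,
                                      stringsAsFactors = FALSE),
    confounder_score = setNames(mod$confounder_score, samples),
    confounder_species = species[sort(conf_species)],
    planted_case = samples[planted_case],
    sample_depth = setNames(depth, samples),
    species_relabund = relab,
    phenotype_coefficients = NULL)
  list(counts = counts, truth = truth)
}

# expected read count of each gene in each sample:
# depth_s * relabund[species(g), s] * length_g / sum(lengths in species(g))
.gene_rate_matrix <- function(catalog, relab, depth) {
  sp_of_gene <- attr(catalog, "species_of_gene")
  len <- catalog$genes$length_bp
  share <- len / ave(len, sp_of_gene, FUN = sum)
  rate <- relab[sp_of_gene, , drop = FALSE] * share
  rate <- sweep(rate, 2L, depth, "*")
  rownames(rate) <- catalog$genes$gene_id
  rate
}

#' Generate a synthetic cohort table with glucose phenotypes
#'
#' Glucose at 0/60/120 min is an affine function of the standardized true
#' per-sample log ratio of case-enriched to control-enriched species
#' abundance plus Gaussian noise; the slope scales with
#' `effect_log2fc / 2 * glucose_coupling` so that a null effect yields a
#' null phenotype. The group label is `case` for the `n_case` samples
#' with the highest fasting glucose (quantile cut), mirroring a
#' threshold-based diagnosis. PBMI is log-normal and age normal.
#'
#' @param config The [synthetic_config()].
#' @param truth The truth record from [generate_counts()].
#' @param counts The matching count matrix (supplies sample ids).
#' @return `list(cohort, truth)`: a data.frame (sample_id, group,
#'   glucose_0, glucose_60, glucose_120, pbmi, age) and the truth record
#'   updated with the phenotype coefficients.
#' @export
generate_cohort <- function(config, truth, counts) {
  stopifnot(inherits(config, "synthetic_config"))
  samples <- colnames(counts)
  n <- length(samples)
  set.seed(derive_seed(config$seed, "cohort"))

  ds <- truth$differential_species
  ce <- ds$taxon_id[ds$direction == "case"]
  ctr <- ds$taxon_id[ds$direction == "control"]
  if (!length(ce) || !length(ctr)) {
    stop("degenerate phenotype model: need differential species in both directions")
  }
  rel <- truth$species_relabund
  lratio <- log(colSums(rel[ce, , drop = FALSE]) /
                colSums(rel[ctr, , drop = FALSE]))
  if (sd(lratio) == 0) stop("degenerate phenotype model: all-equal abundance ratios")
  z <- (lratio - mean(lratio)) / sd(lratio)

  slopes <- .glucose_base_slopes *
    (config$effect_log2fc / .reference_effect) * config$glucose_coupling
  glu <- vapply(names(slopes), function(k) {
    .glucose_intercepts[[k]] + slopes[[k]] * z + rnorm(n, 0, config$phenotype_noise_sd)
  }, numeric(n))

  grp <- rep("control", n)
  grp[order(-glu[, "glucose_0"], samples)[seq_len(config$n_case)]] <- "case"

  cohort <- data.frame(
    sample_id = samples, group = grp,
    glucose_0 = glu[, "glucose_0"], glucose_60 = glu[, "glucose_60"],
    glucose_120 = glu[, "glucose_120"],
    pbmi = round(rlnorm(n, log(21), 0.12), 1),
    age = round(rnorm(n, 29, 3.5), 1),
    stringsAsFactors = FALSE)
  truth$phenotype_coefficients <- list(intercepts = .glucose_intercepts,
                                       slopes = slopes,
                                       noise_sd = config$phenotype_noise_sd)
  truth$true_log_ratio <- setNames(lratio, samples)
  list(cohort = cohort, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: catalogue, counts + truth, cohort.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `"mgwas_dataset"` with `catalog`, `counts`,
#'   `cohort`, `truth`, and the `config`.
#' @export
#' @examples
#' ds <- simulate_dataset(synthetic_config(n_case = 8, n_control = 8,
#'   n_species = 6, genes_per_species = 5, depth_mean = 2e4))
#' dim(ds$counts)
simulate_dataset <- function(config) {
  catalog <- generate_catalog(config)
  cc <- generate_counts(catalog, config)
  ch <- generate_cohort(config, cc$truth, cc$counts)
  structure(list(catalog = catalog, counts = cc$counts, cohort = ch$cohort,
                 truth = ch$truth, config = config),
            class = "mgwas_dataset")
}

#' Monte-Carlo Bayes-optimal AUC of the synthetic generative model
#'
#' Under the generator, the group label is a noisy threshold of the true
#' species log-ratio, so the Bayes-optimal classifier score is monotone
#' in that ratio. This simulates a large cohort from the same species
#' model and returns the AUC of the true log-ratio against the labels --
#' the ceiling any classifier trained on the observed counts can
#' approach.
#'
#' @param config A [synthetic_config()] with `n_diff_species >= 2`.
#' @param n_mc Monte-Carlo cohort size.
#' @param seed Seed for the simulation.
#' @return The Bayes AUC (a number in \[0, 1\]).
#' @export
bayes_auc <- function(config, n_mc = 50000L, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  frac_case <- config$n_case / (config$n_case + config$n_control)
  n_case_mc <- round(n_mc * frac_case)
  set.seed(derive_seed(config$seed, "design"))
  nd <- config$n_diff_species
  diff_sp <- if (nd > 0L) sort(sample(config$n_species, nd)) else integer(0)
  diff_dir <- rep(c("case", "control"), length.out = nd)
  conf_species <- sample(config$n_species, floor(config$n_species / 2))
  if (!any(diff_dir == "case") || !any(diff_dir == "control")) {
    stop("bayes_auc needs differential species in both directions")
  }
  mod <- .species_model(config, n_mc, seq_len(n_case_mc), diff_sp, diff_dir,
                        conf_species, derive_seed(seed, "bayes"))
  rel <- mod$relabund
  lratio <- log(colSums(rel[diff_sp[diff_dir == "case"], , drop = FALSE]) /
                colSums(rel[diff_sp[diff_dir == "control"], , drop = FALSE]))
  z <- (lratio - mean(lratio)) / sd(lratio)
  set.seed(derive_seed(seed, "bayes-noise"))
  slope <- .glucose_base_slopes[["glucose_0"]] *
    (config$effect_log2fc / .reference_effect) * config$glucose_coupling
  glu <- slope * z + rnorm(n_mc, 0, config$phenotype_noise_sd)
  lab <- as.integer(rank(-glu, ties.method = "first") <= n_case_mc)
  .auc_rank(lratio, lab)
}
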