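#' Pipeline configuration
#'
#' All stage parameters with defaults matching the field conventions
#' where one exists (q < 0.05 markers, Spearman network cut 0.4, 30
#' rarefaction draws, 10 000 permutations / trees / bootstraps), each
#' overridable. Input paths may be omitted, in which case the synthetic
#' generator supplies the dataset.
#'
#' @param out_dir Output directory for all artifacts.
#' @param counts,catalog,cohort Optional input TSV paths; all three or
#'   none.
#' @param synth A [synthetic_config()] used when inputs are omitted (its
#'   seed is re-derived from the master seed).
#' @param k_axes,q_threshold Marker-selection parameters.
#' @param rho_min,min_size MLG clustering parameters.
#' @param rho_cut Network edge threshold.
#' @param min_mean_abund_taxa Mean-abundance filter for the genus
#'   comparison (convention 0.05% = 5e-4).
#' @param min_mean_abund_corr Mean-abundance filter for phenotype
#'   correlation panels (convention 0.001% = 1e-5).
#' @param rarefaction_depth Reads per sample for richness; `NULL` uses
#'   the smallest sample total.
#' @param rarefaction_draws Random drawings for richness.
#' @param n_perm PERMANOVA permutations.
#' @param n_trees Random-forest trees.
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @param cv_folds,cv_repeats Cross-validation scheme.
#' @param seed Master seed; every stage seed derives from it via
#'   [derive_seed()].
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, counts = NULL, catalog = NULL,
                            cohort = NULL, synth = synthetic_config(),
                            k_axes = 2L, q_threshold = 0.05, rho_min = 0.7,
                            min_size = 5L, rho_cut = 0.4,
                            min_mean_abund_taxa = 5e-4,
                            min_mean_abund_corr = 1e-5,
                            rarefaction_depth = NULL, rarefaction_draws = 30L,
                            n_perm = 10000L, n_trees = 10000L, n_boot = 10000L,
                            cv_folds = 5L, cv_repeats = 10L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(q_threshold >= 0, q_threshold <= 1, rho_cut >= 0,
            n_perm >= 1, n_trees >= 1, n_boot >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Reads a JSON object whose fields override [pipeline_config()]
#' defaults; a `synth` sub-object overrides [synthetic_config()]
#' defaults.
#'
#' @param path JSON file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  synth_over <- raw$synth
  raw$synth <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg <- do.call(pipeline_config, raw)
  if (!is.null(synth_over)) {
    cfg$synth <- do.call(synthetic_config, synth_over)
  }
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full MGWAS pipeline
#'
#' Executes synth (when no inputs are given) -> profiles -> marker
#' selection -> MLG construction -> association -> classification,
#' writing TSV/JSON/GraphML artifacts and a run manifest into
#' `config$out_dir`. Any stage error aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(packageVersion("mgwas")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config),
                                               c("synth", "out_dir"))],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message("[", stage, "] ", paste(names(list(...)), unlist(list(...)),
                                    sep = "=", collapse = " "))
  }

  # --- inputs -------------------------------------------------------------
  if (is.null(config$counts)) {
    ds <- .stage("synth", {
      sc <- config$synth
      sc$seed <- derive_seed(config$seed, "synth")
      d <- simulate_dataset(sc)
      write_dataset(d, file.path(config$out_dir, "synthetic"))
      d
    })
    catalog <- ds$catalog; counts <- ds$counts; cohort <- ds$cohort
    note("synth", genes = nrow(counts), samples = ncol(counts),
         cases = sum(cohort$group == "case"))
  } else {
    catalog <- .stage("inputs", read_catalog(config$catalog))
    counts <- .stage("inputs", read_counts(config$counts))
    cohort <- .stage("inputs", read_cohort(config$cohort))
    note("inputs", genes = nrow(counts), samples = ncol(counts))
  }

  # --- profiles -----------------------------------------------------------
  prof <- .stage("profiles", {
    abund <- gene_relative_abundance(counts, catalog)
    genus <- taxon_profile(abund, catalog, "genus")
    species <- taxon_profile(abund, catalog, "species")
    ko <- functional_profile(abund, catalog, "KO")
    depth <- config$rarefaction_depth
    if (is.null(depth)) depth <- floor(min(colSums(counts)))
    richness <- rarefied_gene_count(counts, depth, config$rarefaction_draws,
                                    derive_seed(config$seed, "rarefaction"))
    shannon <- shannon_index(abund)
    genus_cmp <- compare_groups(genus, cohort, config$min_mean_abund_taxa)
    .write_matrix_tsv(genus, file.path(config$out_dir, "genus_profile.tsv"), "taxon")
    .write_matrix_tsv(species, file.path(config$out_dir, "species_profile.tsv"), "taxon")
    .write_matrix_tsv(ko, file.path(config$out_dir, "ko_profile.tsv"), "ko")
    .write_tsv(data.frame(sample_id = names(richness), gene_count = richness,
                          shannon = shannon[names(richness)]),
               file.path(config$out_dir, "richness.tsv"))
    .write_tsv(genus_cmp, file.path(config$out_dir, "genus_comparison.tsv"))
    list(abund = abund, genus = genus, species = species)
  })
  note("profiles", genera = nrow(prof$genus), species = nrow(prof$species))

  # --- mgwas --------------------------------------------------------------
  markers <- .stage("mgwas", {
    m <- select_markers(prof$abund, cohort, config$k_axes, config$q_threshold)
    .write_tsv(m, file.path(config$out_dir, "markers.tsv"))
    m
  })
  note("mgwas", tested = attr(markers, "n_tested"),
       skipped = attr(markers, "n_skipped"), selected = nrow(markers))
  if (nrow(markers) == 0L) {
    stop("stage 'mgwas' failed: no markers at q < ", config$q_threshold,
         call. = FALSE)
  }

  # --- mlg ----------------------------------------------------------------
  mlg_res <- .stage("mlg", {
    res <- build_mlgs(prof$abund[markers$gene_id, , drop = FALSE], catalog,
                      cohort, config$rho_min, config$min_size)
    if (nrow(res$table)) {
      .write_tsv(res$table, file.path(config$out_dir, "mlgs.tsv"))
      .write_matrix_tsv(res$abundance,
                        file.path(config$out_dir, "mlg_abundance.tsv"), "mlg_id")
      .write_tsv(do.call(rbind, lapply(res$mlgs, function(m) {
        data.frame(mlg_id = m$mlg_id, gene_id = m$members,
                   stringsAsFactors = FALSE)
      })), file.path(config$out_dir, "mlg_members.tsv"))
    }
    res
  })
  note("mlg", n_mlg = nrow(mlg_res$table),
       unclustered = length(attr(mlg_res$mlgs, "unclustered")))

  # --- association --------------------------------------------------------
  assoc <- .stage("association", {
    out <- list()
    if (nrow(mlg_res$table) >= 2L) {
      edges <- mlg_network(mlg_res$abundance, config$rho_cut)
      .write_tsv(edges, file.path(config$out_dir, "edges.tsv"))
      write_network_graphml(edges, file.path(config$out_dir, "network.graphml"))
      out$edges <- edges
    }
    dirs <- setNames(mlg_res$table$direction, mlg_res$table$mlg_id)
    if (any(dirs == "case-enriched") && any(dirs == "control-enriched")) {
      ratio <- gross_abundance_ratio(mlg_res$abundance, dirs)
      glu_cols <- intersect(c("glucose_0", "glucose_60", "glucose_120"),
                            names(cohort))
      idx <- match(names(ratio), cohort$sample_id)
      ratio_tab <- do.call(rbind, lapply(glu_cols, function(ph) {
        st <- spearman_test(ratio, cohort[[ph]][idx])
        data.frame(phenotype = ph, spearman_rho = st$rho, spearman_p = st$p,
                   pearson_r = suppressWarnings(cor(ratio, cohort[[ph]][idx],
                                                    use = "complete.obs")),
                   stringsAsFactors = FALSE)
      }))
      .write_tsv(data.frame(sample_id = names(ratio), ratio = ratio),
                 file.path(config$out_dir, "gross_ratio.tsv"))
      .write_tsv(ratio_tab, file.path(config$out_dir, "gross_ratio_glucose.tsv"))
      out$ratio <- ratio
    } else {
      message("gross abundance ratio skipped: need both enrichment directions")
    }
    if (!is.null(mlg_res$abundance)) {
      corr <- feature_phenotype_correlation(mlg_res$abundance, cohort,
                                            min_mean_abund = config$min_mean_abund_corr)
      .write_tsv(corr, file.path(config$out_dir, "mlg_phenotype_correlation.tsv"))
    }
    D <- bray_curtis(prof$genus)
    perma <- permanova(D, cohort, config$n_perm,
                       derive_seed(config$seed, "permanova"))
    ord <- dbrda(D, cohort, features = prof$genus)
    .write_tsv(data.frame(sample_id = rownames(ord$scores), ord$scores),
               file.path(config$out_dir, "ordination_scores.tsv"))
    .write_tsv(data.frame(pseudo_f = perma$pseudo_f, p = perma$p,
                          n_perm = perma$n_perm),
               file.path(config$out_dir, "permanova.tsv"))
    out$permanova <- perma
    out
  })
  note("association", pseudo_f = round(assoc$permanova$pseudo_f, 3),
       permanova_p = assoc$permanova$p,
       edges = if (is.null(assoc$edges)) 0L else nrow(assoc$edges))

  # --- classify -----------------------------------------------------------
  cls <- .stage("classify", {
    feats <- if (!is.null(mlg_res$abundance) && nrow(mlg_res$table) >= 2L) {
      mlg_res$abundance
    } else prof$species
    curve <- subset_auc_curve(feats, cohort, cv_folds = config$cv_folds,
                              cv_repeats = config$cv_repeats,
                              n_trees = config$n_trees,
                              seed = derive_seed(config$seed, "classify"))
    ci <- roc_auc_ci(attr(curve, "best_scores"), attr(curve, "labels"),
                     n_boot = config$n_boot,
                     seed = derive_seed(config$seed, "auc-ci"))
    cov_cmp <- if ("pbmi" %in% names(cohort)) {
      classify_with_covariate(feats, cohort, "pbmi",
                              cv_folds = config$cv_folds,
                              cv_repeats = config$cv_repeats,
                              n_trees = config$n_trees,
                              n_boot = min(config$n_boot, 1000L),
                              seed = derive_seed(config$seed, "covariate"))
    }
    report <- list(
      feature_ranking = attr(curve, "ranking"),
      auc_curve = as.list(as.data.frame(curve)),
      best_size = attr(curve, "best_size"),
      auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
      roc = as.list(ci$roc),
      cv_scheme = sprintf("%d-fold stratified CV repeated %d times, pooled out-of-fold scores",
                          config$cv_folds, config$cv_repeats),
      ranking_note = attr(curve, "ranking_bias_note"),
      covariate_comparison = if (!is.null(cov_cmp)) {
        as.list(as.data.frame(cov_cmp))
      })
    jsonlite::write_json(report, file.path(config$out_dir, "classifier_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  })
  note("classify", best_size = cls$best_size, auc = round(cls$auc, 3))

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `profile`, `mgwas`, `mlg`, `associate`,
#' `classify`, `all`. Each stage subcommand reads the TSV interchange
#' files and writes its artifacts; `all` runs [run_pipeline()].
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Invisibly, the result of the invoked stage.
#' @export
mgwas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    stop("usage: mgwas <simulate|profile|mgwas|mlg|associate|classify|all> [options]")
  }
  sub <- args[[1L]]
  rest <- args[-1L]
  opt_list <- list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "pipeline config JSON"),
    optparse::make_option("--counts", type = "character", default = NULL),
    optparse::make_option("--catalog", type = "character", default = NULL),
    optparse::make_option("--cohort", type = "character", default = NULL),
    optparse::make_option("--features", type = "character", default = NULL,
                          help = "feature abundance TSV (classify)"),
    optparse::make_option("--markers", type = "character", default = NULL,
                          help = "markers TSV (mlg)"),
    optparse::make_option("--out", type = "character", default = "mgwas_out",
                          help = "output directory [default %default]"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--k-axes", type = "integer", default = 2L,
                          dest = "k_axes"),
    optparse::make_option("--q", type = "double", default = 0.05),
    optparse::make_option("--rho-min", type = "double", default = 0.7,
                          dest = "rho_min"),
    optparse::make_option("--min-size", type = "integer", default = 5L,
                          dest = "min_size"),
    optparse::make_option("--rho-cut", type = "double", default = 0.4,
                          dest = "rho_cut"),
    optparse::make_option("--n-perm", type = "integer", default = 10000L,
                          dest = "n_perm"),
    optparse::make_option("--n-trees", type = "integer", default = 10000L,
                          dest = "n_trees"),
    optparse::make_option("--n-boot", type = "integer", default = 10000L,
                          dest = "n_boot"),
    optparse::make_option("--covariate", type = "character", default = "pbmi"),
    optparse::make_option("--rank", type = "character", default = "genus"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                              args = rest)
  dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)

  base_config <- function() {
    cfg <- if (!is.null(opt$config)) read_pipeline_config(opt$config)
           else pipeline_config(out_dir = opt$out)
    cfg$out_dir <- opt$out
    for (f in c("counts", "catalog", "cohort")) {
      if (!is.null(opt[[f]])) cfg[[f]] <- opt[[f]]
    }
    for (f in c("seed", "k_axes", "rho_min", "min_size", "rho_cut",
                "n_perm", "n_trees", "n_boot")) {
      cfg[[f]] <- opt[[f]]
    }
    cfg$q_threshold <- opt$q
    cfg
  }

  res <- switch(
    sub,
    simulate = {
      cfg <- base_config()
      sc <- cfg$synth
      sc$seed <- derive_seed(cfg$seed, "synth")
      write_dataset(simulate_dataset(sc), opt$out)
    },
    profile = {
      catalog <- read_catalog(opt$catalog)
      counts <- read_counts(opt$counts)
      abund <- gene_relative_abundance(counts, catalog)
      tax <- taxon_profile(abund, catalog, opt$rank)
      .write_matrix_tsv(tax, file.path(opt$out, paste0(opt$rank, "_profile.tsv")),
                        "taxon")
      if (!is.null(opt$cohort)) {
        cmp <- compare_groups(tax, read_cohort(opt$cohort), 5e-4)
        .write_tsv(cmp, file.path(opt$out, paste0(opt$rank, "_comparison.tsv")))
      }
      tax
    },
    mgwas = {
      catalog <- read_catalog(opt$catalog)
      counts <- read_counts(opt$counts)
      cohort <- read_cohort(opt$cohort)
      abund <- gene_relative_abundance(counts, catalog)
      m <- select_markers(abund, cohort, opt$k_axes, opt$q)
      message("tested=", attr(m, "n_tested"), " skipped=", attr(m, "n_skipped"),
              " selected=", nrow(m))
      .write_tsv(m, file.path(opt$out, "markers.tsv"))
      m
    },
    mlg = {
      catalog <- read_catalog(opt$catalog)
      counts <- read_counts(opt$counts)
      cohort <- read_cohort(opt$cohort)
      abund <- gene_relative_abundance(counts, catalog)
      markers <- read.delim(opt$markers, stringsAsFactors = FALSE)
      res <- build_mlgs(abund[markers$gene_id, , drop = FALSE], catalog, cohort,
                        opt$rho_min, opt$min_size)
      .write_tsv(res$table, file.path(opt$out, "mlgs.tsv"))
      if (!is.null(res$abundance)) {
        .write_matrix_tsv(res$abundance, file.path(opt$out, "mlg_abundance.tsv"),
                          "mlg_id")
      }
      res$table
    },
    associate = {
      ab <- read_counts(opt$features)  # feature x sample TSV
      cohort <- read_cohort(opt$cohort)
      edges <- mlg_network(ab, opt$rho_cut)
      .write_tsv(edges, file.path(opt$out, "edges.tsv"))
      write_network_graphml(edges, file.path(opt$out, "network.graphml"))
      corr <- feature_phenotype_correlation(ab, cohort)
      .write_tsv(corr, file.path(opt$out, "phenotype_correlation.tsv"))
      edges
    },
    classify = {
      feats <- read_counts(opt$features)
      cohort <- read_cohort(opt$cohort)
      curve <- subset_auc_curve(feats, cohort, n_trees = opt$n_trees,
                                seed = opt$seed)
      ci <- roc_auc_ci(attr(curve, "best_scores"), attr(curve, "labels"),
                       n_boot = opt$n_boot, seed = opt$seed)
      report <- list(auc_curve = as.list(as.data.frame(curve)),
                     best_size = attr(curve, "best_size"),
                     auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high)
      jsonlite::write_json(report, file.path(opt$out, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      report
    },
    all = run_pipeline(base_config()),
    stop("unknown subcommand: ", sub))
  invisible(res)
}
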