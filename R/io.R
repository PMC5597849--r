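#' Write a synthetic dataset to plain-text files
#'
#' Serializes a dataset as the pipeline's on-disk interchange format:
#' `catalog.tsv` (gene_id, length_bp, taxon_id, genus, phylum,
#' dna_identity, protein_identity, coverage, ko_id, module_id,
#' pathway_id), `counts.tsv` (gene x sample integers), `cohort.tsv`, and
#' `truth.json`.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mgwas_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat_flat <- merge(dataset$catalog$annotations, dataset$catalog$genes,
                    by = "gene_id", sort = FALSE)
  cat_flat <- cat_flat[order(cat_flat$gene_id),
                       c("gene_id", "length_bp", "taxon_id", "genus", "phylum",
                         "dna_identity", "protein_identity", "coverage",
                         "ko_id", "module_id", "pathway_id")]
  cat_flat$dna_identity <- round(cat_flat$dna_identity, 4)
  cat_flat$protein_identity <- round(cat_flat$protein_identity, 4)
  cat_flat$coverage <- round(cat_flat$coverage, 4)
  .write_tsv(cat_flat, file.path(dir, "catalog.tsv"))
  .write_matrix_tsv(dataset$counts, file.path(dir, "counts.tsv"), "gene_id")
  .write_tsv(dataset$cohort, file.path(dir, "cohort.tsv"))
  truth <- dataset$truth
  truth$species_relabund <- NULL  # large; reconstructible from config + seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a gene catalogue table
#'
#' Reads a `catalog.tsv` as written by [write_dataset()] (one or more
#' annotation rows per gene) into a `"gene_catalog"` object.
#'
#' @param path Path to the TSV.
#' @return A `"gene_catalog"` list with `genes` and `annotations`.
#' @export
read_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp", "taxon_id", "genus", "phylum",
            "dna_identity", "protein_identity", "coverage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  for (opt in c("ko_id", "module_id", "pathway_id")) {
    if (is.null(df[[opt]])) df[[opt]] <- NA_character_
  }
  genes <- df[!duplicated(df$gene_id),
              c("gene_id", "length_bp", "ko_id", "module_id", "pathway_id")]
  ann <- df[, c("gene_id", "taxon_id", "genus", "phylum",
                "dna_identity", "protein_identity", "coverage")]
  structure(list(genes = genes, annotations = ann,
                 species = unique(ann[, c("taxon_id", "genus", "phylum")])),
            class = "gene_catalog")
}

#' Read a genes x samples read-count matrix
#'
#' @param path Path to a TSV whose first column is `gene_id` and whose
#'   remaining columns are per-sample non-negative integer counts.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  if (any(m < 0)) stop("negative read counts in ", path)
  m
}

#' Read a cohort table
#'
#' @param path Path to a TSV with columns sample_id, group, glucose_0,
#'   glucose_60, glucose_120, pbmi, age.
#' @return A data.frame.
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in cohort")
  df
}

#' Read a truth record written by [write_dataset()]
#'
#' @param path Path to `truth.json`.
#' @return A list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
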