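#' Write a trial dataset to plain-text files
#'
#' Emits `clinical.csv` (one row per patient: baseline and week-16 visit
#' components, treatment, populations), `histology.csv`, a genes-by-
#' samples `counts.tsv` (plus optional MatrixMarket `counts.mtx` with
#' `genes.txt` / `samples.txt` sidecars), `gene_sets.gmt` and a JSON
#' `manifest.json` listing the files, their md5 checksums and the seed.
#' Writing then reading with [read_dataset()] reproduces the dataset.
#'
#' @param dataset a `trial_dataset`.
#' @param directory output directory (created if absent).
#' @param overwrite refuse to overwrite an existing manifest unless TRUE.
#' @param mtx also write the MatrixMarket representation.
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(dataset, directory, overwrite = FALSE, mtx = FALSE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  manifest_path <- file.path(directory, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("refusing to overwrite existing dataset; use overwrite = TRUE")
  p <- dataset$patients
  hist_cols <- c("patient_id", "cd20", "cd3", "cd68_lining", "cd68_sublining",
                 "cd138", "cd20_aggregates", "cd21_fdc_networks",
                 "tissue_gradable", "histology_label")
  clin_cols <- setdiff(names(p), setdiff(hist_cols, "patient_id"))
  files <- character()
  utils::write.csv(p[clin_cols], file.path(directory, "clinical.csv"),
                   row.names = FALSE)
  files <- c(files, "clinical.csv")
  utils::write.csv(p[hist_cols], file.path(directory, "histology.csv"),
                   row.names = FALSE)
  files <- c(files, "histology.csv")
  if (!is.null(dataset$expression)) {
    counts <- dataset$expression$counts
    utils::write.table(data.frame(gene_id = rownames(counts), counts,
                                  check.names = FALSE),
                       file.path(directory, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "counts.tsv")
    if (mtx) {
      Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                      file.path(directory, "counts.mtx"))
      writeLines(rownames(counts), file.path(directory, "genes.txt"))
      writeLines(colnames(counts), file.path(directory, "samples.txt"))
      files <- c(files, "counts.mtx", "genes.txt", "samples.txt")
    }
  }
  if (length(dataset$gene_sets) > 0) {
    write_gmt(dataset$gene_sets, file.path(directory, "gene_sets.gmt"))
    files <- c(files, "gene_sets.gmt")
  }
  manifest <- list(
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(directory, files))), files)),
    seed = if (!is.null(dataset$config)) dataset$config$seed else NA,
    n_patients = nrow(p),
    has_expression = !is.null(dataset$expression)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a trial dataset written by [write_dataset()]
#'
#' @param directory dataset directory containing `manifest.json`.
#' @return A `trial_dataset` (the `config` element is not restored).
#' @export
read_dataset <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(manifest_path)
  clin <- utils::read.csv(file.path(directory, "clinical.csv"),
                          stringsAsFactors = FALSE)
  hist <- utils::read.csv(file.path(directory, "histology.csv"),
                          stringsAsFactors = FALSE)
  patients <- merge(clin, hist, by = "patient_id", sort = FALSE)
  patients <- patients[order(match(patients$patient_id, clin$patient_id)), ]
  rownames(patients) <- NULL
  expr <- NULL
  counts_path <- file.path(directory, "counts.tsv")
  if (file.exists(counts_path)) {
    tab <- utils::read.delim(counts_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab$gene_id
    expr <- list(counts = counts, gene_ids = rownames(counts),
                 sample_ids = colnames(counts))
  }
  gene_sets <- list()
  gmt_path <- file.path(directory, "gene_sets.gmt")
  if (file.exists(gmt_path)) gene_sets <- read_gmt(gmt_path)
  structure(list(patients = patients, expression = expr,
                 gene_sets = gene_sets, config = NULL),
            class = "trial_dataset")
}

#' Write gene sets in GMT format
#'
#' One tab-separated line per set: name, description, then the gene ids.
#'
#' @param gene_sets named list of gene-id character vectors.
#' @param path output file.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(length(names(gene_sets)) == length(gene_sets))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "pathotrial", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: name, description, gene ids, tab-separated.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Read a genes-by-samples count matrix from MatrixMarket files
#'
#' @param mtx_path `.mtx` file.
#' @param genes_path,samples_path one-id-per-line sidecar files.
#' @return Dense integer matrix with dimnames.
#' @export
read_counts_mtx <- function(mtx_path, genes_path, samples_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  rownames(m) <- readLines(genes_path)
  colnames(m) <- readLines(samples_path)
  storage.mode(m) <- "integer"
  m
}
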