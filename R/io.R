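#' Read and write the package's tabular interchange formats
#'
#' All interchange files are tab-delimited text (optionally gzipped on
#' read). Expression tables have the gene (or probe) id in the first column
#' and one column per sample; sample metadata tables have columns
#' `sample_id`, `cohort`, `response` (`RD`/`CR`, `pCR` accepted as `CR`) and
#' optionally `er_status`; probe maps have columns `probe_id`, `gene_id`
#' (empty gene_id = unmapped); annotation tables have columns `gene_id`,
#' `category` (repeated gene ids allowed, many-to-many).
#'
#' @param path File path.
#' @param ds,x Object to write.
#' @name mss-io
NULL

#' @rdname mss-io
#' @export
read_expression_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene_id"
  x
}

#' @rdname mss-io
#' @export
read_sample_metadata <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  x$response <- normalize_response(x$response)
  x
}

#' @rdname mss-io
#' @export
read_probe_map <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(x)[1:2] <- c("probe_id", "gene_id")
  x
}

#' @rdname mss-io
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(x)[1:2] <- c("gene_id", "category")
  x
}

#' @rdname mss-io
#' @export
write_expression_tsv <- function(ds, path) {
  tab <- if (inherits(ds, "expression_dataset")) as_tibble(ds) else
    as_tibble(ds)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname mss-io
#' @export
write_sample_metadata <- function(ds, path) {
  readr::write_tsv(sample_info(ds), path, progress = FALSE)
  invisible(path)
}

#' Convert an expression table + metadata into a dataset
#'
#' @param expr Tibble as returned by [read_expression_tsv()] (first column
#'   gene ids).
#' @param samples Sample metadata table.
#' @return An [expression_dataset()].
#' @export
as_expression_dataset <- function(expr, samples) {
  m <- as_probe_matrix(expr)
  expression_dataset(m, samples)
}

#' Write / read a set of discovered signatures
#'
#' Signatures are stored as one TSV with columns `category`, `list_id`,
#' `gene_id`, `frequency`, `rank`, plus a JSON manifest carrying the run
#' configuration (mode, seed, iteration counts).
#'
#' @param signatures An `mss_signature` tibble.
#' @param dir Output directory (created if needed).
#' @export
write_signatures <- function(signatures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(as_tibble(signatures)[, c("category", "list_id",
                                             "gene_id", "frequency", "rank")],
                   file.path(dir, "signatures.tsv"), progress = FALSE)
  cfg <- attr(signatures, "config")
  if (is.null(cfg)) cfg <- list()
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(dir) {
  sig <- readr::read_tsv(file.path(dir, "signatures.tsv"),
                         col_types = "cicii", progress = FALSE)
  manifest <- file.path(dir, "manifest.json")
  cfg <- if (file.exists(manifest)) jsonlite::read_json(manifest) else list()
  new_signature_tibble(sig, config = cfg)
}
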