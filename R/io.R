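#' Read and write the screen's file formats
#'
#' Count matrices travel as TSV (first column `gene_id`, one column per
#' sample) or MatrixMarket (`.mtx` plus `<stem>.genes.txt` /
#' `<stem>.samples.txt` id files); sample sheets and truth tables as CSV;
#' regional and stage tables as long-format TSV.
#'
#' @name msz_io
NULL

#' @param counts gene x sample matrix with dimnames.
#' @param path output path; for MatrixMarket the `.mtx` path, with id files
#'   written alongside.
#' @param format `"tsv"` or `"mtx"`.
#' @rdname msz_io
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_count_matrix(counts)
  if (format == "tsv") {
    df <- tibble::as_tibble(counts, rownames = "gene_id")
    readr::write_tsv(df, path)
  } else {
    m <- Matrix::Matrix(counts, sparse = TRUE)
    Matrix::writeMM(m, path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  }
  invisible(path)
}

#' @rdname msz_io
#' @export
read_count_matrix <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  } else {
    m <- Matrix::readMM(path)
    stem <- sub("\\.mtx$", "", path)
    counts <- as.matrix(m)
    rownames(counts) <- readLines(paste0(stem, ".genes.txt"))
    colnames(counts) <- readLines(paste0(stem, ".samples.txt"))
  }
  check_count_matrix(counts)
  counts
}

#' @param sheet sample sheet tibble (sample_id, color, method, replicate).
#' @rdname msz_io
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path)
  invisible(path)
}

#' @rdname msz_io
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             color = readr::col_character(),
                             method = readr::col_character(),
                             replicate = readr::col_integer()))
  validate_sample_sheet(sheet)
  sheet
}

validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "color", "method", "replicate")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(sheet$color %in% c("red", "white"))) {
    stop("sample sheet colors must be 'red' or 'white'", call. = FALSE)
  }
  key <- paste(sheet$method, sheet$replicate, sheet$color)
  if (anyDuplicated(key) || anyDuplicated(sheet$sample_id)) {
    stop("each (method, replicate, color) and sample_id must be unique",
         call. = FALSE)
  }
  invisible(sheet)
}

#' @param table long-format regional (gene_id, region, value) or stage
#'   (gene_id, stage, timepoint, region, value) table.
#' @rdname msz_io
#' @export
write_long_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname msz_io
#' @export
read_regional_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "region", "value") %in% names(tab)))
  check_region_names(tab$region)
  tab
}

#' @rdname msz_io
#' @export
read_stage_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene_id", "stage", "timepoint", "region", "value")
                %in% names(tab)))
  check_region_names(tab$region)
  tab
}

#' @param truth tibble (gene_id, gene_class).
#' @rdname msz_io
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname msz_io
#' @export
read_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write every component of a synthetic dataset to a directory
#'
#' Produces `counts.tsv` (and optionally `counts.mtx` with id sidecars),
#' `samples.csv`, `regional.tsv`, `stages.tsv` and `truth.csv`.
#'
#' @param dataset an `msz_dataset` from [generate_dataset()].
#' @param outdir output directory (created if needed).
#' @param mtx also write the count matrix in MatrixMarket format.
#' @return `outdir`, invisibly.
#' @export
write_dataset <- function(dataset, outdir, mtx = FALSE) {
  stopifnot(inherits(dataset, "msz_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(dataset$counts, file.path(outdir, "counts.tsv"))
  if (mtx) {
    write_count_matrix(dataset$counts, file.path(outdir, "counts.mtx"),
                       format = "mtx")
  }
  write_sample_sheet(dataset$samples, file.path(outdir, "samples.csv"))
  write_long_table(dataset$regional, file.path(outdir, "regional.tsv"))
  write_long_table(dataset$stages, file.path(outdir, "stages.tsv"))
  write_truth(dataset$truth, file.path(outdir, "truth.csv"))
  invisible(outdir)
}
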