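#' Fixed vocabularies used throughout the screen
#'
#' The six dissected embryonic regions of the localization screen, the three
#' developmental stage classes of the marker criteria, and the planted gene
#' classes recognised by the simulator.
#'
#' @name vocabularies
#' @keywords internal
NULL

#' @rdname vocabularies
#' @export
msz_regions <- function() {
  c("anterior_PS", "anterior_midline", "caudal_neural",
    "anterior_neural", "caudal_PS", "non_neural_ectoderm")
}

#' @rdname vocabularies
#' @export
msz_stages <- function() {
  c("gastrulation", "initiation", "elongation")
}

#' @rdname vocabularies
#' @export
msz_gene_classes <- function() {
  c("msz_marker", "neural", "paraxial", "housekeeping",
    "gastrulation_transient", "anteriorPS_nonspecific",
    "msz_like_transient", "silent")
}

# Regions that must be clear of signal for a gene to pass the regional screen
# (anterior_midline is permitted by default, anterior_PS is required).
disallowed_regions <- function() {
  c("caudal_neural", "anterior_neural", "caudal_PS", "non_neural_ectoderm")
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be a single non-missing number")
  }
  if (strict_lower && x <= lower) {
    stop_field(field, sprintf("must be > %s", lower))
  }
  if (!strict_lower && x < lower) {
    stop_field(field, sprintf("must be >= %s", lower))
  }
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

check_named_per_method <- function(x, field, methods, lower = 0,
                                   upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || is.null(names(x))) {
    stop_field(field, "must be a named numeric vector (one value per method)")
  }
  missing <- setdiff(methods, names(x))
  if (length(missing) > 0L) {
    stop_field(field, paste0("missing value for method(s): ",
                             paste(missing, collapse = ", ")))
  }
  for (m in methods) {
    check_scalar_number(x[[m]], paste0(field, "[", m, "]"),
                        lower = lower, upper = upper,
                        strict_lower = strict_lower)
  }
  invisible(x)
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric gene x sample matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("gene ids (rownames) must be unique", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("sample ids (colnames) must be unique", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  invisible(counts)
}

check_region_names <- function(regions) {
  unknown <- setdiff(unique(regions), msz_regions())
  if (length(unknown) > 0L) {
    stop(paste0("unknown region name(s): ", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  invisible(regions)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
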