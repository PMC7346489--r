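#' Trait code vocabulary
#'
#' The five milk-production trait codes used throughout the package:
#' `MY` milk yield, `PY` protein yield, `FY` fat yield, `PP` protein
#' percentage, `FP` fat percentage.
#'
#' @return Character vector of the five allowed trait codes.
#' @export
#' @examples
#' trait_codes()
trait_codes <- function() c("MY", "PY", "FY", "PP", "FP")

#' Normalize a chromosome label
#'
#' Strips a leading "Chr"/"chr"/"BTA" prefix (case-insensitive) and
#' surrounding whitespace, so that `"Chr18"`, `"chr18"`, `"BTA18"` and
#' `"18"` all map to `"18"`. Non-autosome labels such as `"X"` pass
#' through unchanged. The operation is idempotent.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_chrom(c("Chr18", "BTA18", "18", "chrX"))
normalize_chrom <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^(chr|bta)[[:space:]]*", "", x, ignore.case = TRUE)
  if (any(!nzchar(x))) {
    stop("chromosome label empty after normalization", call. = FALSE)
  }
  x
}

# Round half away from zero at `digits` decimals. base::round() rounds half
# to even, which does not reproduce the printed distance labels.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific sub-seed from one master seed (kept < 2^31).
split_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k)
}

# Internal validator: stop with a named-field message unless condition holds.
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Path to a packaged evidence fixture
#'
#' Convenience accessor for the plain-text evidence tables shipped under
#' `inst/extdata/` (the transcribed bovine milk-trait QTL/SNP catalogues and
#' the top differentially expressed genes). Called with no arguments it
#' lists the available files.
#'
#' @param file File name within the package's `extdata` directory, or
#'   `NULL` to list all fixtures.
#' @return A file path (or character vector of file names).
#' @export
#' @examples
#' candgene_fixture()
candgene_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "candgene")
  if (is.null(file)) {
    return(list.files(dir))
  }
  path <- file.path(dir, file)
  check_that(file.exists(path), paste0("no packaged fixture named '", file, "'"))
  path
}
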