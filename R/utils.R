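#' Deterministic integer hash of an integer vector
#'
#' Polynomial rolling hash over 31-bit arithmetic, used to fold circular
#' atom-environment descriptors into sparse feature identifiers. All
#' intermediates stay below 2^53 so the computation is exact in doubles and
#' identical across platforms.
#'
#' @param x integer (or integer-valued numeric) vector
#' @return a single non-negative integer-valued double < 2^31 - 1
#' @keywords internal
hash_ints <- function(x) {
  m <- 2147483647 # 2^31 - 1
  h <- 17
  for (v in x) {
    h <- (h * 1000003 + (v %% m)) %% m
  }
  h
}

#' Canonicalize a microtiter well address
#'
#' Accepts "A1" and zero-padded "A01" dialects (any case); returns the
#' unpadded upper-case form ("A1").
#'
#' @param well character vector of well addresses
#' @return character vector of canonical addresses
#' @export
canonical_well <- function(well) {
  well <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-P](0?[1-9]|1[0-9]|2[0-4])$", well)
  if (any(!ok)) {
    stop("malformed well address(es): ", paste(well[!ok], collapse = ", "))
  }
  row <- substr(well, 1, 1)
  col <- as.integer(substring(well, 2))
  paste0(row, col)
}

#' Split canonical well addresses into row index and column number
#' @keywords internal
well_row_col <- function(well) {
  well <- canonical_well(well)
  list(
    row = match(substr(well, 1, 1), LETTERS),
    col = as.integer(substring(well, 2))
  )
}

#' All well addresses for a plate geometry
#'
#' @param geometry 96 (8 rows x 12 columns) or 384 (16 x 24)
#' @return character vector of canonical addresses in row-major order
#' @export
plate_wells <- function(geometry = 96) {
  geometry <- as.integer(geometry)
  dims <- switch(as.character(geometry),
    "96"  = c(8L, 12L),
    "384" = c(16L, 24L),
    stop("plate geometry must be 96 or 384, got ", geometry)
  )
  as.vector(t(outer(LETTERS[seq_len(dims[1])], seq_len(dims[2]), paste0)))
}

#' Stable content hash of an R object (for run metadata / stage skipping)
#' @keywords internal
config_hash <- function(x) {
  s <- jsonlite::serializeJSON(x, digits = 15)
  hash_ints(utf8ToInt(as.character(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
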