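#' Construct and validate a plate layout
#'
#' A layout maps each well of a 96- or 384-well microtiter plate to its role
#' in the screen: a compound well (with compound identifier and dose), a
#' solvent (DMSO) control, or an empty well. Screening plates must carry at
#' least four solvent-control wells so that the in-plate control AUC is a
#' stable reference.
#'
#' @param plate_id plate identifier
#' @param wells data.frame with columns `well`, `role`
#'   (one of "compound", "solvent_control", "empty"), and for compound wells
#'   `compound_id` and `dose_uM`
#' @param geometry plate geometry, 96 or 384
#' @param min_controls minimum number of solvent-control wells required on a
#'   plate that carries any compound well (default 4)
#' @return an object of class `plate_layout`
#' @export
plate_layout <- function(plate_id, wells, geometry = 96, min_controls = 4) {
  stopifnot(is.data.frame(wells), all(c("well", "role") %in% names(wells)))
  wells$well <- canonical_well(wells$well)
  if (anyDuplicated(wells$well)) {
    stop("duplicate well address(es) in layout for plate ", plate_id, ": ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  }
  ok_roles <- c("compound", "solvent_control", "empty")
  if (!all(wells$role %in% ok_roles)) {
    stop("unknown role(s): ",
         paste(setdiff(unique(wells$role), ok_roles), collapse = ", "))
  }
  universe <- plate_wells(geometry)
  if (!all(wells$well %in% universe)) {
    stop("well(s) outside ", geometry, "-well geometry: ",
         paste(setdiff(wells$well, universe), collapse = ", "))
  }
  if (is.null(wells$compound_id)) wells$compound_id <- NA_character_
  if (is.null(wells$dose_uM)) wells$dose_uM <- NA_real_
  wells$compound_id <- as.character(wells$compound_id)
  wells$dose_uM <- as.numeric(wells$dose_uM)
  is_cpd <- wells$role == "compound"
  if (any(is_cpd & (is.na(wells$compound_id) | wells$compound_id == ""))) {
    stop("compound wells without compound_id in plate ", plate_id)
  }
  wells$dose_uM[is_cpd & is.na(wells$dose_uM)] <- 25
  n_ctrl <- sum(wells$role == "solvent_control")
  if (any(is_cpd) && n_ctrl < min_controls) {
    stop("plate ", plate_id, " carries compounds but only ", n_ctrl,
         " solvent control(s); at least ", min_controls, " required")
  }
  structure(
    list(plate_id = as.character(plate_id),
         geometry = as.integer(geometry),
         wells = wells[, c("well", "role", "compound_id", "dose_uM")]),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("plate_layout", x$plate_id, sprintf("(%d-well):", x$geometry),
      sum(x$wells$role == "compound"), "compound,",
      sum(x$wells$role == "solvent_control"), "control,",
      sum(x$wells$role == "empty"), "empty wells\n")
  invisible(x)
}

#' Read a plate layout from delimited text
#'
#' Expected columns: `well,role,compound_id,dose_uM` (compound_id/dose may be
#' blank for controls and empties). The plate identifier defaults to the file
#' name without extension.
#'
#' @param path path to a CSV/TSV layout file
#' @param plate_id plate identifier; default taken from the file name
#' @param geometry plate geometry, 96 or 384
#' @return a `plate_layout`
#' @export
read_layout <- function(path, plate_id = NULL, geometry = 96) {
  df <- read_delim_auto(path)
  plate_layout(plate_id %||% sub("\\.[^.]*$", "", basename(path)),
               df, geometry = geometry)
}

#' A single well's optical-density time course
#'
#' @param plate_id plate identifier
#' @param well canonical well address
#' @param times timepoints in hours, strictly increasing, length >= 2
#' @param od optical-density readings, same length as `times`, finite, >= 0
#' @return an object of class `well_series`
#' @export
well_series <- function(plate_id, well, times, od) {
  times <- as.numeric(times)
  od <- as.numeric(od)
  if (length(times) < 2 || length(times) != length(od)) {
    stop("well ", well, ": need >= 2 paired time/OD readings")
  }
  if (any(diff(times) <= 0)) {
    stop("well ", well, ": timepoints must be strictly increasing")
  }
  if (any(!is.finite(od)) || any(od < 0)) {
    stop("well ", well, ": OD readings must be finite and >= 0")
  }
  structure(list(plate_id = as.character(plate_id),
                 well = canonical_well(well),
                 times = times, od = od),
            class = "well_series")
}

#' @export
print.well_series <- function(x, ...) {
  cat(sprintf("well_series %s/%s: %d readings over %.1f h, OD %.3f..%.3f\n",
              x$plate_id, x$well, length(x$times), max(x$times) - min(x$times),
              min(x$od), max(x$od)))
  invisible(x)
}

# sniff comma vs tab and read with headers as-is
read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, strip.white = TRUE,
                    colClasses = "character")
}

#' Read a plate-reader growth table
#'
#' The file is delimited text with a `well` column and one column per
#' timepoint; the header row gives the times (optionally prefixed with "t",
#' e.g. `t0,t0.5,...`). Wells present in the layout but absent from the file
#' are reported with a warning; wells in the file but not in the layout are
#' rejected.
#'
#' @param path path to the growth table
#' @param layout the plate's `plate_layout`
#' @param time_unit "hours" (default) or "minutes"; minute headers are
#'   converted to hours
#' @return list of `well_series`, one per non-empty layout well found in the
#'   file, with attribute `missing_wells`
#' @export
read_growth_table <- function(path, layout, time_unit = c("hours", "minutes")) {
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(layout, "plate_layout"))
  df <- read_delim_auto(path)
  if (!"well" %in% names(df)) stop("growth table ", path, " lacks a 'well' column")
  tidx <- which(names(df) != "well") # positions, so duplicate headers surface
  tcols <- names(df)[tidx]
  times <- suppressWarnings(as.numeric(sub("^[tT]", "", tcols)))
  if (any(is.na(times))) {
    stop("growth table ", path, ": non-numeric time header(s): ",
         paste(tcols[is.na(times)], collapse = ", "))
  }
  if (any(diff(times) <= 0)) {
    stop("growth table ", path, ": header times are not strictly increasing")
  }
  if (time_unit == "minutes") times <- times / 60
  file_wells <- canonical_well(df$well)
  expected <- layout$wells$well[layout$wells$role != "empty"]
  extraneous <- setdiff(file_wells, expected)
  if (length(extraneous)) {
    stop("growth table ", path, ": well(s) not in layout (or empty): ",
         paste(extraneous, collapse = ", "))
  }
  missing <- setdiff(expected, file_wells)
  if (length(missing)) {
    warning("growth table ", path, ": layout well(s) absent from file: ",
            paste(missing, collapse = ", "))
  }
  series <- vector("list", length(file_wells))
  for (i in seq_along(file_wells)) {
    od <- suppressWarnings(as.numeric(df[i, tidx]))
    if (any(is.na(od))) {
      bad <- which(is.na(od))[1]
      stop("growth table ", path, ": non-numeric OD in well ", file_wells[i],
           " at timepoint ", tcols[bad])
    }
    series[[i]] <- well_series(layout$plate_id, file_wells[i], times, od)
  }
  names(series) <- file_wells
  attr(series, "missing_wells") <- missing
  series
}

#' Write well series back to the growth-table format
#'
#' Values are written at full double precision so a write/read round trip
#' reproduces times and OD exactly.
#'
#' @param series list of `well_series` sharing one time grid
#' @param path output CSV path
#' @export
write_growth_table <- function(series, path) {
  stopifnot(length(series) >= 1)
  times <- series[[1]]$times
  for (s in series) {
    if (!identical(s$times, times)) {
      stop("all series must share one time grid to be written as a table")
    }
  }
  header <- c("well", paste0("t", format(times, digits = 17, trim = TRUE,
                                         scientific = FALSE)))
  rows <- vapply(series, function(s) {
    paste(c(s$well, format(s$od, digits = 17, trim = TRUE,
                           scientific = FALSE)), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' Read a compound library
#'
#' Accepts either delimited text with `compound_id` and `smiles` columns
#' (optional `library`, `screen_dose_uM`), or a plain SMILES file
#' (`SMILES<tab>id`, one record per line, extension `.smi`). Records whose
#' SMILES cannot be parsed are dropped and counted in the rejection report.
#'
#' @param path path to the library file
#' @param library_name library label used when the file does not carry one
#' @param validate parse every SMILES and drop invalid records (default TRUE)
#' @return data.frame with columns compound_id, smiles, library,
#'   screen_dose_uM; attribute `rejected` holds the dropped compound ids
#' @export
read_compound_library <- function(path, library_name = NULL, validate = TRUE) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    df <- data.frame(
      compound_id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
      smiles = vapply(parts, `[`, "", 1),
      stringsAsFactors = FALSE
    )
    if (anyNA(df$compound_id)) {
      df$compound_id[is.na(df$compound_id)] <-
        paste0("CPD", which(is.na(df$compound_id)))
    }
  } else {
    df <- read_delim_auto(path)
    if (!all(c("compound_id", "smiles") %in% names(df))) {
      stop("compound library ", path, " needs compound_id and smiles columns")
    }
  }
  df$library <- if (!is.null(df$library)) as.character(df$library) else
    (library_name %||% sub("\\.[^.]*$", "", basename(path)))
  df$screen_dose_uM <- if (!is.null(df$screen_dose_uM))
    as.numeric(df$screen_dose_uM) else 25
  dup <- duplicated(paste(df$library, df$compound_id))
  if (any(dup)) {
    stop("duplicate compound_id within library: ",
         paste(unique(df$compound_id[dup]), collapse = ", "))
  }
  rejected <- character(0)
  if (validate && nrow(df)) {
    can <- canonical_smiles(df$smiles)
    bad <- is.na(can)
    if (any(bad)) {
      warning(sum(bad), " record(s) with unparseable SMILES dropped: ",
              paste(df$compound_id[bad], collapse = ", "))
      rejected <- df$compound_id[bad]
      df <- df[!bad, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  out <- df[, c("compound_id", "smiles", "library", "screen_dose_uM")]
  attr(out, "rejected") <- rejected
  out
}

#' Write a compound table as a plain SMILES file (`SMILES<tab>id`)
#' @param compounds data.frame with `smiles` and `compound_id`
#' @param path output path
#' @export
write_smiles_file <- function(compounds, path) {
  writeLines(paste(compounds$smiles, compounds$compound_id, sep = "\t"), path)
  invisible(path)
}
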