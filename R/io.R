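# required event-record columns and their types
.er_cols <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "WT", "CRCL",
              "COUNTRY")

#' Validate an event-record table
#'
#' Checks the pharmacometric event-record invariants: dose rows (`EVID = 1`)
#' carry `AMT > 0` and `MDV = 1`; observation rows (`EVID = 0`) carry no
#' `AMT` and, when `MDV = 0`, a non-negative `DV`; `TIME` is non-decreasing
#' within subject; covariates are constant within subject. Violations raise
#' a row-indexed error.
#'
#' @param x Event-record tibble.
#' @return `x`, invisibly.
#' @export
validate_pk_dataset <- function(x) {
  missing_cols <- setdiff(.er_cols, names(x))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x$EVID == 1 & (is.na(x$AMT) | x$AMT <= 0 | x$MDV != 1))
  if (length(bad)) {
    stop("dose rows must have AMT > 0 and MDV = 1; rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(x$EVID == 0 & !is.na(x$AMT))
  if (length(bad)) {
    stop("observation rows must not carry AMT; rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(x$EVID == 0 & x$MDV == 0 & (is.na(x$DV) | x$DV < 0))
  if (length(bad)) {
    stop("non-missing observations must have DV >= 0; rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (id in unique(x$ID)) {
    d <- x[x$ID == id, ]
    if (is.unsorted(d$TIME)) {
      stop("TIME must be non-decreasing within subject ", id, call. = FALSE)
    }
    if (length(unique(d$WT)) > 1 || length(unique(d$CRCL)) > 1 ||
        length(unique(d$COUNTRY)) > 1) {
      stop("covariates must be constant within subject ", id, call. = FALSE)
    }
  }
  invisible(x)
}

#' Read / write event-record datasets
#'
#' The canonical on-disk dialect is comma-separated with a header row, dot
#' decimals, lowercase country strings, time in hours from first dose, and
#' empty fields for missing `AMT`/`DV`. `read_pk_dataset()` validates the
#' invariants and reports per-subject record counts;
#' `write_pk_dataset()` writes the canonical dialect so that a write/read
#' cycle round-trips.
#'
#' @param path File path.
#' @return `read_pk_dataset()`: a validated tibble with a `subjects`
#'   attribute (per-subject dose/observation counts).
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         ID = readr::col_integer(),
                         TIME = readr::col_double(),
                         AMT = readr::col_double(),
                         DV = readr::col_double(),
                         EVID = readr::col_integer(),
                         MDV = readr::col_integer(),
                         WT = readr::col_double(),
                         CRCL = readr::col_double(),
                         COUNTRY = readr::col_character()
                       ))
  validate_pk_dataset(x)
  counts <- x |>
    dplyr::group_by(.data$ID) |>
    dplyr::summarise(n_dose = sum(.data$EVID == 1),
                     n_obs = sum(.data$EVID == 0 & .data$MDV == 0),
                     .groups = "drop")
  attr(x, "subjects") <- counts
  x
}

#' @rdname read_pk_dataset
#' @param x Event-record tibble.
#' @export
write_pk_dataset <- function(x, path) {
  validate_pk_dataset(x)
  out <- x[, .er_cols]
  # canonical 12-significant-digit formatting so that a write/read cycle is
  # byte-stable
  num <- c("TIME", "AMT", "DV", "WT", "CRCL")
  for (cl in num) {
    v <- formatC(out[[cl]], digits = 12, format = "g")
    v[is.na(out[[cl]])] <- ""
    out[[cl]] <- v
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write the generating truth of a synthetic dataset
#'
#' Sidecar files for a dataset from [generate_pk_dataset()] /
#' [generate_study_dataset()]: the per-subject truth (covariates and true
#' random effects) as CSV and the generating parameters as YAML.
#'
#' @param dataset Tibble with a `truth` attribute.
#' @param stem Output path stem; writes `<stem>_truth.csv` and
#'   `<stem>_params.yaml`.
#' @return The two paths, invisibly.
#' @export
write_truth_sidecar <- function(dataset, stem) {
  truth <- attr(dataset, "truth")
  if (is.null(truth)) stop("dataset carries no truth attribute", call. = FALSE)
  p1 <- paste0(stem, "_truth.csv")
  p2 <- paste0(stem, "_params.yaml")
  readr::write_csv(truth$population, p1)
  write_pk_parameters(truth$params, p2)
  invisible(c(p1, p2))
}
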