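#' Read an event-record concentration dataset
#'
#' Reads the pharmacometric event-record CSV convention used throughout the
#' package: one row per dose (`EVID = 1`) or observation (`EVID = 0`).
#' Columns (case-insensitive): `ID`, `TIME` (h), `AMT` (mg, doses only),
#' `II` (h, optional; a repeating steady-state regimen), `DV` (ng/mL,
#' observations only), `EVID`, `MDV`, `WT` (kg), `ZOP` (0/1), optional
#' `TROUGH` and extra covariate columns. Units are fixed at the interface;
#' nothing is auto-detected or imputed.
#'
#' @param path CSV file path.
#' @return A validated `clz_dataset` tibble.
#' @seealso [write_pk_dataset()], [simulate_cohort()]
#' @export
read_pk_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))
  as_pk_dataset(raw)
}

#' Write an event-record dataset to CSV
#'
#' @param dataset A `clz_dataset` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  out <- dataset
  attr(out, "meta") <- NULL
  attr(out, "truth") <- NULL
  class(out) <- class(tibble::tibble())
  names(out) <- toupper(names(out))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Validate a data frame as an event-record dataset
#'
#' Checks the event-record invariants row by row and fails with the first
#' offending row number: dose rows (`evid = 1`) need `amt >= 0` and missing
#' `dv`; observation rows (`evid = 0`) need `dv` present with `mdv = 0`;
#' weight must be positive and constant within subject; `zop` must be 0/1.
#'
#' @param x Data frame with (lower- or upper-case) event-record columns.
#' @return The validated `clz_dataset` tibble.
#' @export
as_pk_dataset <- function(x) {
  x <- tibble::as_tibble(x)
  attr(x, "truth") <- NULL # generative ground truth never survives import
  attr(x, "meta") <- NULL
  names(x) <- tolower(names(x))
  required <- c("id", "time", "amt", "dv", "evid", "mdv", "wt", "zop")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$ii)) x$ii <- NA_real_
  if (is.null(x$trough)) x$trough <- NA
  for (col in c("time", "amt", "dv", "evid", "mdv", "wt", "zop", "ii")) {
    if (!is.numeric(x[[col]]) && !all(is.na(x[[col]]))) {
      stop(sprintf("column '%s' is not numeric", col), call. = FALSE)
    }
  }
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      stop(sprintf("row %d: %s", idx[1], what), call. = FALSE)
    }
  }
  bad_row(!x$evid %in% c(0L, 1L), "EVID must be 0 or 1")
  bad_row(x$evid == 1L & (is.na(x$amt) | x$amt < 0),
          "dose row (EVID=1) needs AMT >= 0")
  bad_row(x$evid == 1L & !is.na(x$dv), "dose row (EVID=1) must have blank DV")
  bad_row(x$evid == 0L & is.na(x$dv), "observation row (EVID=0) needs DV")
  bad_row(x$evid == 0L & x$mdv != 0L, "observation row (EVID=0) needs MDV=0")
  bad_row(is.na(x$time) | x$time < 0, "TIME must be >= 0")
  bad_row(is.na(x$wt) | x$wt <= 0, "WT must be positive")
  bad_row(!x$zop %in% c(0, 1), "ZOP must be 0 or 1")
  wt_n <- tapply(x$wt, x$id, function(w) length(unique(w)))
  if (any(wt_n > 1)) {
    stop("WT must be constant within subject (id ",
         names(wt_n)[which(wt_n > 1)[1]], ")", call. = FALSE)
  }
  zero_obs <- setdiff(unique(x$id), unique(x$id[x$evid == 0L]))
  if (length(zero_obs)) {
    stop("subject(s) without observations: ",
         paste(utils::head(zero_obs, 3), collapse = ", "), call. = FALSE)
  }
  class(x) <- c("clz_dataset", class(x))
  x
}

# Per-subject covariate table of a dataset (one row per id, first-row values).
dataset_covariates <- function(dataset) {
  core <- c("id", "time", "amt", "ii", "dv", "evid", "mdv", "trough")
  dataset |>
    dplyr::group_by(.data$id) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("id", weight = "wt", "zop",
                  dplyr::any_of(setdiff(names(dataset), c(core, "wt", "zop"))))
}
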