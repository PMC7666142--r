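ABUNDANCE_COLUMNS <- c("season", "treatment", "replicate", "group",
                       "time_h", "cells_per_ml")

validate_abundance <- function(tbl, source = "abundance table") {
  missing_cols <- setdiff(ABUNDANCE_COLUMNS, names(tbl))
  if (length(missing_cols)) {
    stop(source, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(tbl$time_h)) {
    stop(source, ": `time_h` must be numeric", call. = FALSE)
  }
  if (!is.numeric(tbl$cells_per_ml)) {
    stop(source, ": `cells_per_ml` must be numeric (a decimal-comma file? ",
         "the expected dialect is comma-separated with dot decimals)",
         call. = FALSE)
  }
  neg_t <- which(tbl$time_h < 0)
  if (length(neg_t)) {
    stop(source, ": negative time_h in row(s) ",
         paste(utils::head(neg_t, 5), collapse = ", "), call. = FALSE)
  }
  neg_n <- which(tbl$cells_per_ml < 0 | !is.finite(tbl$cells_per_ml))
  if (length(neg_n)) {
    stop(source, ": negative or non-finite cells_per_ml in row(s) ",
         paste(utils::head(neg_n, 5), collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(tbl[c("season", "treatment", "replicate",
                                "group", "time_h")], sep = "\r"))
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup)) {
    stop(source, ": duplicated observation key in row(s) ",
         paste(dup, collapse = ", "),
         " (each season/treatment/replicate/group/time_h must be unique)",
         call. = FALSE)
  }
  invisible(tbl)
}

#' Read a tidy abundance CSV
#'
#' Expects a comma-separated, dot-decimal, UTF-8 file with a header row
#' naming the six canonical columns `season`, `treatment`, `replicate`,
#' `group`, `time_h`, `cells_per_ml`. Validation failures (missing
#' columns, non-numeric abundance, negative times, duplicate observation
#' keys) raise errors naming the offending rows (data rows, excluding the
#' header).
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @seealso [write_abundance_csv()]
#' @export
read_abundance_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(ABUNDANCE_COLUMNS, names(tbl))
  if (length(missing_cols)) {
    stop(basename(path), ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("time_h", "cells_per_ml")) {
    raw <- tbl[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad)) {
      hint <- if (any(grepl(",", raw[bad]))) {
        " (decimal commas? the expected dialect is comma-separated with dot decimals)"
      } else {
        ""
      }
      stop(basename(path), ": non-numeric `", col, "` in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), hint,
           call. = FALSE)
    }
    tbl[[col]] <- num
  }
  validate_abundance(tbl, source = basename(path))
  tbl[ABUNDANCE_COLUMNS]
}

#' Write a tidy abundance CSV
#'
#' @param tbl Abundance tibble (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(tbl, path) {
  validate_abundance(tbl)
  readr::write_csv(tbl[ABUNDANCE_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Packaged in situ reference tables
#'
#' Three small fixtures transcribed from the study's printed summary
#' tables of a NW Mediterranean coastal seasonal experiment series:
#' \describe{
#'   \item{`table1`}{Physicochemical and biological parameters of the
#'     initial samples, one row per variable with one numeric column per
#'     season; sampling dates are kept in `attr(, "dates")`.}
#'   \item{`table2`}{In situ contribution of each probe-defined group to
#'     total DAPI counts (percent), per season, with SDs where printed.}
#'   \item{`table3`}{Minimal and maximal growth rates (day^-1) per group
#'     and experiment, including earlier studies at the same site, the
#'     overall `Range` rows and their printed max-min spreads.}
#' }
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`.
#' @return A tibble.
#' @examples
#' load_fixture("table3")
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, c("table1", "table2", "table3"))
  path <- system.file("extdata", paste0(name, ".csv"), package = "ratepart",
                      mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (name == "table1") {
    dates <- unlist(tbl[tbl$variable == "date", SEASON_LEVELS])
    tbl <- tbl[tbl$variable != "date", ]
    for (col in SEASON_LEVELS) tbl[[col]] <- as.numeric(tbl[[col]])
    attr(tbl, "dates") <- dates
  } else {
    num <- setdiff(names(tbl), c("group", "date", "source"))
    for (col in num) tbl[[col]] <- as.numeric(tbl[[col]])
  }
  tbl
}
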