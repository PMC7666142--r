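#' Net growth rate from one abundance time course
#'
#' The net growth rate is the slope of ordinary least squares regression
#' of ln(cells mL^-1) on time over the interval of exponential growth,
#' converted from h^-1 to day^-1. `mode = "full"` uses every point (the
#' default: with no stated window-selection rule, the whole series is the
#' transparent choice). `mode = "best_window"` scans every contiguous
#' sub-series of at least `min_points` observations and keeps the one with
#' the highest r-squared, breaking ties toward the longer window and then
#' the earlier start — a simple automated stand-in for choosing the
#' visually exponential interval. With exactly two points the slope is the
#' two-point log difference and r-squared is undefined.
#'
#' @param times_h Sampling times in hours.
#' @param cells Abundances, cells mL^-1; all must be strictly positive
#'   (a zero count has no logarithm and the observation carries no usable
#'   rate information — see the methods vignette).
#' @param min_points Minimum window length for `best_window` (default 3).
#' @param mode `"full"` or `"best_window"`.
#'
#' @return A one-row tibble: `k` (day^-1), `t_start_h`, `t_end_h`,
#'   `n_points`, `r_squared` (`NA` when `n_points == 2`), `mode`.
#'
#' @examples
#' t <- c(0, 12, 24, 36)
#' fit_exponential_window(t, 1e5 * exp(0.05 * t)) # k = 1.2 day^-1
#' @export
fit_exponential_window <- function(times_h, cells, min_points = 3L,
                                   mode = c("full", "best_window")) {
  mode <- match.arg(mode)
  if (length(times_h) != length(cells)) {
    stop("`times_h` and `cells` must have equal length", call. = FALSE)
  }
  if (length(times_h) < 2L) {
    stop("at least 2 observations are required", call. = FALSE)
  }
  if (anyDuplicated(times_h)) {
    stop("sampling times must be distinct", call. = FALSE)
  }
  bad <- which(!is.finite(cells) | cells <= 0)
  if (length(bad)) {
    stop("non-positive abundance at index ", paste(bad, collapse = ", "),
         "; ln-linear regression requires positive counts", call. = FALSE)
  }
  ord <- order(times_h)
  t <- times_h[ord]
  y <- log(cells[ord])
  n <- length(t)

  if (mode == "full" || min_points >= n) {
    fit <- ols_slope(t, y)
    return(tibble::tibble(
      k = fit$slope * 24, t_start_h = t[1], t_end_h = t[n],
      n_points = n, r_squared = fit$r_squared, mode = mode
    ))
  }

  min_points <- max(2L, as.integer(min_points))
  best <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      len <- j - i + 1L
      if (len < min_points) next
      if (j > n) next
      fit <- ols_slope(t[i:j], y[i:j])
      # undefined r^2 (constant series) ranks below any defined fit but
      # still ties with other undefined windows so length breaks the tie
      r2 <- if (is.na(fit$r_squared)) -1 else fit$r_squared
      cand <- list(i = i, j = j, len = len, r2 = r2, fit = fit)
      if (is.null(best) ||
          cand$r2 > best$r2 + 1e-12 ||
          (abs(cand$r2 - best$r2) <= 1e-12 &&
             (cand$len > best$len ||
                (cand$len == best$len && cand$i < best$i)))) {
        best <- cand
      }
    }
  }
  tibble::tibble(
    k = best$fit$slope * 24, t_start_h = t[best$i], t_end_h = t[best$j],
    n_points = best$len,
    r_squared = best$fit$r_squared, mode = mode
  )
}

# slope and r^2 of y ~ x by the textbook sums; r^2 is NA for n = 2 (a
# two-point fit is exact by construction) and for constant y (slope 0, no
# variance to explain)
ols_slope <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  sxy <- sum(xc * yc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  r2 <- if (n <= 2L) NA_real_ else if (syy <= 0) NA_real_ else sxy^2 / (sxx * syy)
  list(slope = slope, r_squared = r2)
}

#' Estimate net growth rates for a tidy abundance table
#'
#' Fits [fit_exponential_window()] to each (season, treatment, group,
#' replicate) series. Series containing non-positive counts, or with fewer
#' than two usable points, are skipped and reported in the `gaps`
#' attribute rather than failing the whole table.
#'
#' @param abundance Tidy table with columns `season`, `treatment`,
#'   `replicate`, `group`, `time_h`, `cells_per_ml` (see
#'   [read_abundance_csv()] or [make_experiment()]).
#' @inheritParams fit_exponential_window
#'
#' @return A tibble with one row per series: the grouping keys plus `k`,
#'   `t_start_h`, `t_end_h`, `n_points`, `r_squared`, `mode`. Skipped
#'   series are recorded in `attr(, "gaps")` (a tibble with a `reason`
#'   column). Use [mean_rates()] for replicate means and SDs and
#'   [rate_gaps()] for missing treatment coverage.
#' @export
estimate_rates <- function(abundance, mode = c("full", "best_window"),
                           min_points = 3L) {
  mode <- match.arg(mode)
  validate_abundance(abundance)
  keys <- c("season", "treatment", "group", "replicate")
  split_idx <- split(seq_len(nrow(abundance)), abundance[keys], drop = TRUE)

  rows <- vector("list", length(split_idx))
  gaps <- list()
  for (nm in seq_along(split_idx)) {
    idx <- split_idx[[nm]]
    sub <- abundance[idx, ]
    key <- sub[1, keys]
    fit <- tryCatch(
      fit_exponential_window(sub$time_h, sub$cells_per_ml,
                             min_points = min_points, mode = mode),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      gaps[[length(gaps) + 1L]] <-
        dplyr::bind_cols(key, tibble::tibble(reason = conditionMessage(fit)))
    } else {
      rows[[nm]] <- dplyr::bind_cols(key, fit)
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$season, .data$treatment, .data$group,
                        .data$replicate)
  attr(out, "gaps") <- dplyr::bind_rows(gaps)
  out
}

#' Replicate-mean net growth rates
#'
#' @param estimates Per-replicate table from [estimate_rates()].
#' @return A tibble with `season`, `treatment`, `group`, `k_mean`, `k_sd`
#'   (`NA` for a single replicate) and `n_replicates`, matching how such
#'   experiments report rates (mean with SD over triplicate bottles).
#' @export
mean_rates <- function(estimates) {
  stopifnot(all(c("season", "treatment", "group", "k") %in%
                  names(estimates)))
  dplyr::summarise(
    dplyr::group_by(estimates, .data$season, .data$treatment, .data$group),
    k_mean = mean(.data$k), k_sd = stats::sd(.data$k),
    n_replicates = dplyr::n(), .groups = "drop"
  )
}

#' Report missing treatment coverage per group
#'
#' A group enumerated in some treatments but absent in others (as AAP are,
#' counted only in the control and predator-reduced bottles) cannot enter
#' every downstream comparison; this reports each (season, group) with the
#' treatments it lacks, against either the treatments observed in the
#' table or an explicit expected set.
#'
#' @param estimates Table with `season`, `treatment`, `group` columns.
#' @param expected Character vector of treatment codes that full coverage
#'   means; defaults to all treatments present in `estimates`.
#' @return A tibble with `season`, `group`, `missing_treatments`
#'   (comma-separated); zero rows when coverage is complete.
#' @export
rate_gaps <- function(estimates,
                      expected = sort(unique(estimates$treatment))) {
  dplyr::filter(
    dplyr::summarise(
      dplyr::group_by(estimates, .data$season, .data$group),
      missing_treatments = paste(setdiff(expected, .data$treatment),
                                 collapse = ","),
      .groups = "drop"
    ),
    .data$missing_treatments != ""
  )
}

#' Absolute abundance of a group from its DAPI fraction
#'
#' Links probe-positive fractions of total DAPI counts to absolute
#' abundances: `cells = fraction * dapi_total`.
#'
#' @param fraction_of_dapi Fraction in \[0, 1\].
#' @param dapi_total Total DAPI count, cells mL^-1.
#' @return Cells mL^-1.
#' @examples
#' group_absolute_abundance(0.435, 1.04e6)
#' @export
group_absolute_abundance <- function(fraction_of_dapi, dapi_total) {
  if (any(fraction_of_dapi < 0 | fraction_of_dapi > 1)) {
    stop("`fraction_of_dapi` must lie in [0, 1]", call. = FALSE)
  }
  if (any(dapi_total < 0)) stop("`dapi_total` must be >= 0", call. = FALSE)
  fraction_of_dapi * dapi_total
}

#' Aerobic anoxygenic phototroph count from paired images
#'
#' AAP are enumerated as infrared-positive cells minus the Chl
#' a-containing organisms that also show in the infrared image. A negative
#' difference (possible with noisy counts of rare cells) is clamped to
#' zero with a warning.
#'
#' @param infrared_positive,chl_positive Non-negative cell counts.
#' @return Count of AAP cells.
#' @examples
#' aap_count(120, 20)
#' @export
aap_count <- function(infrared_positive, chl_positive) {
  if (any(infrared_positive < 0) || any(chl_positive < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  diff <- infrared_positive - chl_positive
  if (any(diff < 0)) {
    warning("infrared count below Chl a count; clamping AAP count at 0",
            call. = FALSE)
  }
  pmax(diff, 0)
}

#' Convert leucine incorporation to carbon production
#'
#' Biomass production from tritiated-leucine uptake using a
#' leucine-to-carbon conversion factor:
#' pmol Leu L^-1 h^-1 x 1e-12 mol/pmol x ccf kgC/mol x 1e9 ug/kg x
#' 24 h/day.
#'
#' @param leu_pmol_per_l_per_h Leucine incorporation rate, >= 0.
#' @param ccf_kgc_per_mol Conversion factor, kgC per mol leucine
#'   (1.5 is typical of NW Mediterranean coastal water).
#' @return Production in ugC L^-1 day^-1.
#' @examples
#' leucine_to_production(100, 1.5) # 3.6
#' @export
leucine_to_production <- function(leu_pmol_per_l_per_h,
                                  ccf_kgc_per_mol = 1.5) {
  if (any(leu_pmol_per_l_per_h < 0) || any(ccf_kgc_per_mol < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  leu_pmol_per_l_per_h * 1e-12 * ccf_kgc_per_mol * 1e9 * 24
}
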