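#' Forward model: net growth rates implied by a mortality partition
#'
#' The four light-cycle treatments impose a linear budget on the net growth
#' rate of a population growing exponentially at gross rate `mu` and losing
#' cells to grazing (`m_g`), resource limitation (`r_c`) and viral lysis
#' (`m_v`), all in day^-1:
#'
#' \deqn{k_{CT} = \mu - (m_g + r_c + m_v)}
#' \deqn{k_{PR} = \mu - (r_c + m_v)}
#' \deqn{k_{DI} = \mu - (D m_g + D r_c + m_v)}
#' \deqn{k_{VR} = \mu - D (m_g + r_c + m_v)}
#'
#' where `D` is the dilution factor. This is the forward model used by the
#' synthetic-experiment generator and the verification oracle for
#' [solve_partition()].
#'
#' @param mu Gross growth rate, day^-1.
#' @param m_g Grazing mortality, day^-1.
#' @param r_c Resource-limitation constraint on growth, day^-1.
#' @param m_v Viral mortality, day^-1.
#' @param D Dilution factor in (0, 1); default 0.25.
#'
#' @return A tibble with columns `k_ct`, `k_pr`, `k_di`, `k_vr` (day^-1)
#'   and `D`. Vectorised over the rate arguments.
#'
#' @examples
#' predict_net_rates(mu = 1.1, m_g = 0.4, r_c = 8 / 15, m_v = 1 / 15)
#' @seealso [solve_partition()] for the inverse.
#' @export
predict_net_rates <- function(mu, m_g, r_c, m_v, D = 0.25) {
  check_dilution_factor(D)
  check_finite(mu, "mu")
  check_finite(m_g, "m_g")
  check_finite(r_c, "r_c")
  check_finite(m_v, "m_v")
  mu <- unname(mu); m_g <- unname(m_g)
  r_c <- unname(r_c); m_v <- unname(m_v)
  tibble::tibble(
    k_ct = mu - (m_g + r_c + m_v),
    k_pr = mu - (r_c + m_v),
    k_di = mu - (D * m_g + D * r_c + m_v),
    k_vr = mu - D * (m_g + r_c + m_v),
    D    = D
  )
}

#' Partition net growth rates into gross growth and loss terms
#'
#' Inverts the four-treatment budget of [predict_net_rates()] in closed
#' form. The system is triangular once differenced:
#' `m_g = k_pr - k_ct`, `m_v = (k_vr - k_di) / (1 - D)`,
#' `r_c = (k_di - k_pr + D * m_g) / (1 - D)` and
#' `mu = k_pr + r_c + m_v`.
#'
#' Measurement noise can drive individual components negative (the study
#' design itself produces VR/DI ratios below one, i.e. negative viral-loss
#' estimates). Negative components are reported as computed and flagged in
#' the `negative_components` column; set `truncate_negative = TRUE` to clamp
#' them at zero instead (the clamped solution no longer reproduces the
#' input rates).
#'
#' @param k_ct,k_pr,k_di,k_vr Net growth rates (day^-1) in the control,
#'   predator-reduced, diluted and virus-reduced light treatments.
#'   Vectorised.
#' @param D Dilution factor in (0, 1).
#' @param truncate_negative Clamp negative loss components at zero.
#'
#' @return A tibble with columns `mu`, `m_g`, `r_c`, `m_v`, `D`,
#'   `negative_components` (comma-separated names, `NA` when none) and
#'   `truncated` (logical).
#'
#' @examples
#' solve_partition(k_ct = 0.1, k_pr = 0.5, k_di = 0.8, k_vr = 0.85)
#' @export
solve_partition <- function(k_ct, k_pr, k_di, k_vr, D = 0.25,
                            truncate_negative = FALSE) {
  check_dilution_factor(D)
  check_finite(k_ct, "k_ct")
  check_finite(k_pr, "k_pr")
  check_finite(k_di, "k_di")
  check_finite(k_vr, "k_vr")
  k_ct <- unname(k_ct); k_pr <- unname(k_pr)
  k_di <- unname(k_di); k_vr <- unname(k_vr)

  m_g <- k_pr - k_ct
  m_v <- (k_vr - k_di) / (1 - D)
  r_c <- (k_di - k_pr + D * m_g) / (1 - D)
  mu  <- k_pr + r_c + m_v

  comp <- cbind(m_g = m_g, r_c = r_c, m_v = m_v)
  neg <- apply(comp, 1L, function(row) {
    bad <- names(row)[row < 0]
    if (length(bad)) paste(bad, collapse = ",") else NA_character_
  })

  if (truncate_negative) {
    m_g <- pmax(m_g, 0)
    r_c <- pmax(r_c, 0)
    m_v <- pmax(m_v, 0)
  }

  tibble::tibble(
    mu = mu, m_g = m_g, r_c = r_c, m_v = m_v, D = D,
    negative_components = neg,
    truncated = truncate_negative
  )
}

#' Response ratio between two treatments
#'
#' The ratio of mean net growth rates between two treatments quantifies the
#' release from one pressure: PR/CT for grazing, DI/PR for resource
#' competition, VR/DI for viruses and light/dark for PAR exposure. A ratio
#' above 1 indicates faster growth once the pressure is reduced; the 1:1
#' line means equal magnitude in both treatments.
#'
#' Ratios are undefined when the denominator rate is at or below `epsilon`
#' (near-zero or negative control rates would produce unbounded or
#' sign-flipped ratios); the value is then missing with the reason
#' recorded, and the rate difference `k_num - k_den` is reported either
#' way.
#'
#' @param k_num,k_den Net growth rates (day^-1) in the numerator and
#'   denominator treatments. Vectorised.
#' @param kind One of `"grazing"` (PR/CT), `"resources"` (DI/PR),
#'   `"viruses"` (VR/DI), `"light"` (L/D).
#' @param epsilon Smallest denominator (day^-1) for which a ratio is
#'   reported; default 1e-6.
#'
#' @return A tibble with columns `kind`, `value` (ratio, `NA` when
#'   undefined), `difference` (`k_num - k_den`, always present),
#'   `numerator`, `denominator` and `reason` (`NA` or
#'   `"denominator <= epsilon"`).
#'
#' @examples
#' response_ratio(0.5, 0.1, "grazing")
#' response_ratio(0.3, -0.05, "resources") # missing value, difference kept
#' @export
response_ratio <- function(k_num, k_den,
                           kind = c("grazing", "resources", "viruses",
                                    "light"),
                           epsilon = 1e-6) {
  kind <- match.arg(kind)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  check_finite(k_num, "k_num")
  check_finite(k_den, "k_den")
  ok <- k_den > epsilon
  tibble::tibble(
    kind        = kind,
    value       = ifelse(ok, k_num / k_den, NA_real_),
    difference  = k_num - k_den,
    numerator   = k_num,
    denominator = k_den,
    reason      = ifelse(ok, NA_character_, "denominator <= epsilon")
  )
}

# Treatment pairs behind each response-ratio kind (numerator / denominator).
RATIO_PAIRS <- list(
  grazing   = c("PR_L", "CT_L"),
  resources = c("DI_L", "PR_L"),
  viruses   = c("VR_L", "DI_L")
)

#' Response ratios for a table of mean net growth rates
#'
#' Computes the four pressure ratios (grazing PR/CT, resources DI/PR,
#' viruses VR/DI, and light L/D for the control and predator-reduced
#' pairs) for every group and season present in a mean-rate table such as
#' the one returned by [mean_rates()].
#'
#' @param rate_means Tibble with columns `season`, `group`, `treatment`,
#'   `k_mean`.
#' @param epsilon Passed to [response_ratio()].
#'
#' @return A tibble with one row per season, group and available ratio,
#'   with the treatment pair recorded in `num_treatment`/`den_treatment`.
#' @export
response_ratios <- function(rate_means, epsilon = 1e-6) {
  stopifnot(all(c("season", "group", "treatment", "k_mean") %in%
                  names(rate_means)))
  wide <- tidyr::pivot_wider(
    dplyr::select(rate_means, "season", "group", "treatment", "k_mean"),
    names_from = "treatment", values_from = "k_mean"
  )
  have <- function(cols) all(cols %in% names(wide))
  out <- list()
  for (kind in names(RATIO_PAIRS)) {
    pair <- RATIO_PAIRS[[kind]]
    if (!have(pair)) next
    rows <- !is.na(wide[[pair[1]]]) & !is.na(wide[[pair[2]]])
    if (!any(rows)) next
    rr <- response_ratio(wide[[pair[1]]][rows], wide[[pair[2]]][rows],
                         kind, epsilon)
    out[[kind]] <- dplyr::bind_cols(
      wide[rows, c("season", "group")],
      rr,
      tibble::tibble(num_treatment = pair[1], den_treatment = pair[2])
    )
  }
  # light effect: one ratio per light/dark bottle pair (CT and PR)
  for (pair_base in c("CT", "PR")) {
    pair <- paste0(pair_base, c("_L", "_D"))
    if (!have(pair)) next
    rows <- !is.na(wide[[pair[1]]]) & !is.na(wide[[pair[2]]])
    if (!any(rows)) next
    rr <- response_ratio(wide[[pair[1]]][rows], wide[[pair[2]]][rows],
                         "light", epsilon)
    out[[paste0("light_", pair_base)]] <- dplyr::bind_cols(
      wide[rows, c("season", "group")],
      rr,
      tibble::tibble(num_treatment = pair[1], den_treatment = pair[2])
    )
  }
  dplyr::bind_rows(out)
}

#' Mortality partitions for a table of mean net growth rates
#'
#' Applies [solve_partition()] to every (season, group) with complete
#' coverage of the four light treatments. Partitions are computed on
#' replicate-mean rates by default; `per_replicate = TRUE` instead solves
#' per replicate bottle and then averages the components (both modes are
#' reported with the same columns, plus component SDs in the per-replicate
#' mode).
#'
#' @param rates Per-replicate rate table from [estimate_rates()] (needs
#'   `season`, `group`, `treatment`, `replicate`, `k`), or a mean-rate
#'   table from [mean_rates()] when `per_replicate = FALSE`.
#' @param D Dilution factor in (0, 1).
#' @param truncate_negative Passed to [solve_partition()].
#' @param per_replicate Solve per bottle, then average components.
#'
#' @return A tibble with one row per season and group, the partition
#'   components, and a `complete` flag; groups missing any of the four
#'   light treatments are returned with `complete = FALSE` and `NA`
#'   components rather than dropped.
#' @export
partition_rates <- function(rates, D = 0.25, truncate_negative = FALSE,
                            per_replicate = FALSE) {
  check_dilution_factor(D)
  needed <- c("CT_L", "PR_L", "DI_L", "VR_L")
  if (!"k_mean" %in% names(rates) && !per_replicate) {
    rates <- mean_rates(rates)
  }

  if (per_replicate) {
    stopifnot(all(c("replicate", "k") %in% names(rates)))
    wide <- tidyr::pivot_wider(
      dplyr::select(rates, "season", "group", "replicate", "treatment", "k"),
      names_from = "treatment", values_from = "k"
    )
  } else {
    wide <- tidyr::pivot_wider(
      dplyr::select(rates, "season", "group", "treatment", "k_mean"),
      names_from = "treatment", values_from = "k_mean"
    )
  }
  for (tr in needed) if (!tr %in% names(wide)) wide[[tr]] <- NA_real_
  complete <- stats::complete.cases(wide[needed])

  sol <- solve_partition(
    k_ct = ifelse(complete, wide$CT_L, 0),
    k_pr = ifelse(complete, wide$PR_L, 0),
    k_di = ifelse(complete, wide$DI_L, 0),
    k_vr = ifelse(complete, wide$VR_L, 0),
    D = D, truncate_negative = truncate_negative
  )
  for (col in c("mu", "m_g", "r_c", "m_v")) {
    sol[[col]][!complete] <- NA_real_
  }
  sol$negative_components[!complete] <- NA_character_
  out <- dplyr::bind_cols(
    wide[c("season", "group", intersect("replicate", names(wide)))],
    sol,
    tibble::tibble(complete = complete)
  )
  if (per_replicate) {
    out <- dplyr::summarise(
      dplyr::group_by(out, .data$season, .data$group),
      dplyr::across(c("mu", "m_g", "r_c", "m_v"),
                    list(mean = ~ mean(.x), sd = ~ stats::sd(.x))),
      D = D[1], truncated = truncated[1],
      complete = all(.data$complete), n_replicates = dplyr::n(),
      .groups = "drop"
    )
  }
  out
}

#' Bootstrap uncertainty for a mean-rate mortality partition
#'
#' Resamples replicate bottles with replacement within each (season, group,
#' treatment), recomputes treatment means and re-solves the partition,
#' giving a sampling distribution for each component. The study design
#' reports only replicate means and SDs; this propagates bottle-to-bottle
#' variability through the (linear) solver.
#'
#' @param rates Per-replicate rate table (see [estimate_rates()]).
#' @param D Dilution factor.
#' @param n_boot Number of bootstrap draws (default 999).
#' @param seed Integer seed; draws are reproducible and do not touch the
#'   global RNG stream.
#'
#' @return A tibble with one row per season, group and component, giving
#'   the point estimate, bootstrap SD, and 2.5%/97.5% quantiles.
#' @export
bootstrap_partition <- function(rates, D = 0.25, n_boot = 999, seed = 1L) {
  stopifnot(all(c("season", "group", "treatment", "replicate", "k") %in%
                  names(rates)))
  point <- partition_rates(rates, D = D)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(i) {
      res <- dplyr::slice_sample(
        dplyr::group_by(rates, .data$season, .data$group, .data$treatment),
        prop = 1, replace = TRUE
      )
      res <- dplyr::ungroup(res)
      means <- dplyr::summarise(
        dplyr::group_by(res, .data$season, .data$group, .data$treatment),
        k_mean = mean(.data$k), .groups = "drop"
      )
      p <- partition_rates(means, D = D)
      p$draw <- i
      p
    })
  })
  boot <- dplyr::bind_rows(draws)
  long <- tidyr::pivot_longer(boot, c("mu", "m_g", "r_c", "m_v"),
                              names_to = "component", values_to = "value")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$season, .data$group, .data$component),
    boot_sd = stats::sd(.data$value),
    lower = stats::quantile(.data$value, 0.025, names = FALSE),
    upper = stats::quantile(.data$value, 0.975, names = FALSE),
    .groups = "drop"
  )
  point_long <- tidyr::pivot_longer(point, c("mu", "m_g", "r_c", "m_v"),
                                    names_to = "component",
                                    values_to = "estimate")
  dplyr::left_join(
    dplyr::select(point_long, "season", "group", "component", "estimate"),
    summ,
    by = c("season", "group", "component")
  )
}
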