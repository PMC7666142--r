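#' Specification of one simulated bacterioplankton group
#'
#' Bundles the generating parameters for one probe-defined group: its
#' initial share of total DAPI counts, its gross growth rate, the ambient
#' loss rates partitioned into grazing, resource limitation and viral
#' lysis, and a multiplicative light modifier applied to the gross rate in
#' light-cycle bottles (photoheterotrophy: proteorhodopsin-containing
#' SAR11, aerobic anoxygenic phototrophs).
#'
#' @param name Group identifier, one of
#'   `r paste(GROUP_LEVELS, collapse = ", ")`.
#' @param initial_fraction Fraction of total DAPI counts at t = 0, in
#'   \[0, 1\].
#' @param mu Gross growth rate in the dark, day^-1.
#' @param m_g,r_c,m_v Ambient grazing, resource-limitation and viral loss
#'   rates, day^-1 (non-negative).
#' @param light_modifier Multiplicative factor on `mu` under light (> 0);
#'   1 means no light response.
#' @param parent Enclosing group for nested probes (`ALT`, `NOR5` within
#'   `GAMMA`; `ROSEO`, `SAR11`, `GAMMA`, `CFB` within `EUB`; `EUB` within
#'   `PRK`), or `NA`.
#'
#' @return A one-row tibble of class `group_spec`.
#' @export
group_spec <- function(name, initial_fraction, mu, m_g, r_c, m_v,
                       light_modifier = 1, parent = GROUP_PARENT[[name]]) {
  name <- match.arg(name, GROUP_LEVELS)
  stopifnot(
    is.numeric(initial_fraction), initial_fraction >= 0,
    initial_fraction <= 1,
    is.finite(mu), m_g >= 0, r_c >= 0, m_v >= 0, light_modifier > 0
  )
  out <- tibble::tibble(
    name = name, parent = parent %||% NA_character_,
    initial_fraction = initial_fraction,
    mu = mu, m_g = m_g, r_c = r_c, m_v = m_v,
    light_modifier = light_modifier
  )
  class(out) <- c("group_spec", class(out))
  out
}

check_group_specs <- function(groups) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1L)
  f <- stats::setNames(groups$initial_fraction, groups$name)
  get <- function(g) if (g %in% names(f)) f[[g]] else 0
  if (get("ALT") + get("NOR5") > get("GAMMA") + 1e-12 && "GAMMA" %in% names(f)) {
    stop("nesting violated: ALT + NOR5 initial fractions exceed GAMMA",
         call. = FALSE)
  }
  eub_children <- get("ROSEO") + get("SAR11") + get("GAMMA") + get("CFB")
  if ("EUB" %in% names(f) && eub_children > get("EUB") + 1e-12) {
    stop("nesting violated: ROSEO + SAR11 + GAMMA + CFB exceed EUB",
         call. = FALSE)
  }
  if (any(f > 1)) stop("initial fractions must be <= 1", call. = FALSE)
  invisible(groups)
}

#' Noise model for simulated microscope counts
#'
#' @param model `"lognormal"` (multiplicative, mean-one, the default),
#'   `"poisson"` (field-count shot noise: cells are counted, not measured)
#'   or `"none"`.
#' @param cv Coefficient of variation of the lognormal multiplier
#'   (default 0.10).
#' @param count_scale For the Poisson mode: counted cells per unit of
#'   cells mL^-1, i.e. the product of filter-to-frame geometry and frames
#'   counted. The default 1e-3 yields ~1000 counted cells at
#'   10^6 cells mL^-1.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(model = c("lognormal", "poisson", "none"),
                       cv = 0.10, count_scale = 1e-3) {
  model <- match.arg(model)
  stopifnot(cv >= 0, count_scale > 0)
  structure(list(model = model, cv = cv, count_scale = count_scale),
            class = "noise_spec")
}

#' Design of one simulated seasonal experiment
#'
#' @param season Season label (`"winter"`, `"spring"`, `"summer"`,
#'   `"fall"`).
#' @param total_dapi_t0 Total prokaryote abundance at t = 0,
#'   cells mL^-1.
#' @param duration_h Incubation length in hours (36 or 48 in the study
#'   design).
#' @param sample_times_h Strictly increasing sampling times in hours,
#'   starting at 0; default four evenly spaced points over the duration.
#' @param replicates Number of replicate bottles per treatment (default 3).
#' @param noise A [noise_spec()].
#' @param seed Integer seed; mandatory, so no simulation depends on global
#'   RNG state.
#' @param D Dilution factor for the DI and VR treatments.
#'
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(season, total_dapi_t0, duration_h = 48,
                              sample_times_h = seq(0, duration_h,
                                                   length.out = 4),
                              replicates = 3L, noise = noise_spec(),
                              seed, D = 0.25) {
  season <- match.arg(season, SEASON_LEVELS)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  check_dilution_factor(D)
  stopifnot(
    total_dapi_t0 > 0, duration_h > 0, replicates >= 1L,
    inherits(noise, "noise_spec"),
    length(sample_times_h) >= 2L
  )
  if (sample_times_h[1] != 0 || is.unsorted(sample_times_h, strictly = TRUE)) {
    stop("`sample_times_h` must be strictly increasing and start at 0",
         call. = FALSE)
  }
  if (any(sample_times_h < 0 | sample_times_h > duration_h)) {
    stop("sampling times must lie within [0, duration_h]", call. = FALSE)
  }
  structure(
    list(season = season, total_dapi_t0 = total_dapi_t0,
         duration_h = duration_h, sample_times_h = sample_times_h,
         replicates = as.integer(replicates), noise = noise,
         seed = as.integer(seed), D = D),
    class = "experiment_design"
  )
}

#' Ground-truth net growth rate of a group in a treatment
#'
#' Evaluates the forward budget for one group and one treatment:
#' `k = mu * (light ? light_modifier : 1) - (grazer_factor * m_g +
#' resource_factor * r_c + virus_factor * m_v)`.
#'
#' @param spec A [group_spec()] row (or any list with the rate fields).
#' @param treatment A one-row slice of [treatment_codes()], or a treatment
#'   code string.
#' @param D Dilution factor used when `treatment` is given as a string.
#' @return Net growth rate, day^-1.
#' @examples
#' g <- group_spec("SAR11", 0.4, mu = 1.1, m_g = 0.4, r_c = 8 / 15,
#'                 m_v = 1 / 15)
#' true_net_rate(g, "CT_L") # 0.1
#' @export
true_net_rate <- function(spec, treatment, D = 0.25) {
  if (is.character(treatment)) {
    codes <- treatment_codes(D)
    treatment <- codes[codes$code == match.arg(treatment, codes$code), ]
  }
  mu_eff <- spec$mu * ifelse(treatment$light, spec$light_modifier, 1)
  mu_eff - (treatment$grazer_factor * spec$m_g +
              treatment$resource_factor * spec$r_c +
              treatment$virus_factor * spec$m_v)
}

# Seasonal in situ conditions and group rate defaults. Initial fractions
# and totals come from the packaged in situ tables (see load_fixture);
# leaf-group gross rates equal that season's observed maximum and total
# losses span max - min, split between grazing, resources and viruses with
# season-dependent weights (grazing-dominated winter, resource-dominated
# summer, virus share slightly raised in fall and spring). Aggregate
# probes (GAMMA, EUB, PRK) take the envelope of their nested children so
# that probe sums stay consistent through time (see the methods vignette).
SEASON_LOSS_WEIGHTS <- list(
  winter = c(m_g = 0.70, r_c = 0.15, m_v = 0.15),
  spring = c(m_g = 0.45, r_c = 0.35, m_v = 0.20),
  summer = c(m_g = 0.25, r_c = 0.60, m_v = 0.15),
  fall   = c(m_g = 0.40, r_c = 0.35, m_v = 0.25)
)

# 2017 seasonal rate ranges (day^-1) per group, as packaged in table3.
SEASON_RATE_RANGES <- list(
  winter = list(ROSEO = c(0.5, 1.0), SAR11 = c(0.0, 0.9),
                ALT = c(0.1, 4.9), NOR5 = c(0.2, 0.6), CFB = c(0.1, 1.6),
                AAP = c(0.8, 1.4)),
  spring = list(ROSEO = c(0.1, 0.6), SAR11 = c(0.2, 0.6),
                ALT = c(0.5, 3.0), NOR5 = c(0.3, 1.3), CFB = c(0.2, 1.0),
                AAP = c(0.2, 0.6)),
  summer = list(ROSEO = c(0.4, 0.8), SAR11 = c(0.2, 0.4),
                ALT = c(0.4, 1.9), NOR5 = c(0.7, 1.1), CFB = c(0.4, 0.7),
                AAP = c(0.4, 0.5)),
  fall   = list(ROSEO = c(0.2, 0.6), SAR11 = c(0.0, 0.5),
                ALT = c(0.0, 1.8), NOR5 = c(0.3, 0.7), CFB = c(0.1, 0.5),
                AAP = c(0.5, 1.2))
)

# Light modifiers on the gross rate: SAR11 (proteorhodopsin) responds in
# all seasons; AAP respond in spring/summer and are slightly dark-favoured
# in winter; CFB respond in fall.
SEASON_LIGHT_MODIFIERS <- list(
  winter = c(SAR11 = 1.15, AAP = 0.90),
  spring = c(SAR11 = 1.15, AAP = 1.20),
  summer = c(SAR11 = 1.15, AAP = 1.30, ROSEO = 1.10, NOR5 = 1.10),
  fall   = c(SAR11 = 1.15, CFB = 1.10)
)

SEASON_DURATION_H <- c(winter = 36, spring = 48, summer = 36, fall = 48)

envelope_spec <- function(children, name, initial_fraction) {
  # parent rates must dominate every child's in every treatment so probe
  # sums stay nested over time: max gross rate (per light state),
  # componentwise-min losses
  mu <- max(children$mu)
  lm_ <- max(children$mu * children$light_modifier) / mu
  group_spec(
    name, initial_fraction, mu = mu,
    m_g = min(children$m_g), r_c = min(children$r_c),
    m_v = min(children$m_v), light_modifier = max(lm_, 1e-8)
  )
}

#' Default generating parameters for one seasonal experiment
#'
#' Returns one [group_spec()] per probe-defined group, seeded from the
#' packaged in situ tables: initial fractions are that season's observed
#' contributions to DAPI counts, and leaf-group rates sit inside that
#' season's observed rate ranges. Where the printed in situ fractions are
#' internally inconsistent with probe nesting (the Gammaproteobacteria
#' probe undercounts its *Alteromonadaceae* + NOR5 subgroups in three
#' seasons), the parent fraction is raised to the child sum. Aggregate
#' probes take envelope rates over their children (see the methods
#' vignette for why).
#'
#' @param season One of `"winter"`, `"spring"`, `"summer"`, `"fall"`.
#' @return A tibble of group specifications.
#' @examples
#' default_season_specs("winter")
#' @export
default_season_specs <- function(season) {
  season <- match.arg(season, SEASON_LEVELS)
  tab2 <- load_fixture("table2")
  frac <- stats::setNames(tab2[[paste0(season, "_pct")]] / 100, tab2$group)
  ranges <- SEASON_RATE_RANGES[[season]]
  w <- SEASON_LOSS_WEIGHTS[[season]]
  mods <- SEASON_LIGHT_MODIFIERS[[season]]

  leaf <- function(name) {
    rng <- ranges[[name]]
    loss <- (rng[2] - rng[1])
    group_spec(
      name, frac[[name]], mu = rng[2],
      m_g = w[["m_g"]] * loss, r_c = w[["r_c"]] * loss,
      m_v = w[["m_v"]] * loss,
      light_modifier = if (name %in% names(mods)) mods[[name]] else 1
    )
  }
  leaves <- dplyr::bind_rows(lapply(names(ranges), leaf))

  gamma_children <- leaves[leaves$name %in% c("ALT", "NOR5"), ]
  gamma_frac <- max(frac[["GAMMA"]], sum(gamma_children$initial_fraction))
  gamma <- envelope_spec(gamma_children, "GAMMA", gamma_frac)

  eub_children <- dplyr::bind_rows(
    leaves[leaves$name %in% c("ROSEO", "SAR11", "CFB"), ], gamma
  )
  eub_frac <- max(frac[["EUB"]],
                  sum(eub_children$initial_fraction[
                    eub_children$name %in% c("ROSEO", "SAR11", "CFB", "GAMMA")]))
  eub <- envelope_spec(eub_children, "EUB", eub_frac)
  prk <- envelope_spec(eub, "PRK", 1)

  out <- dplyr::bind_rows(prk, eub, leaves[leaves$name == "ROSEO", ],
                          leaves[leaves$name == "SAR11", ], gamma,
                          gamma_children, leaves[leaves$name == "CFB", ],
                          leaves[leaves$name == "AAP", ])
  out <- out[match(GROUP_LEVELS, out$name), ]
  check_group_specs(out)
  out
}

#' Default experiment design for a season
#'
#' Uses the season's observed total prokaryote abundance and the study's
#' incubation lengths (36 h in winter and summer, 48 h in spring and
#' fall) with four evenly spaced sampling times.
#'
#' @inheritParams experiment_design
#' @export
default_season_design <- function(season, seed, noise = noise_spec(),
                                  replicates = 3L, D = 0.25) {
  season <- match.arg(season, SEASON_LEVELS)
  tab1 <- load_fixture("table1")
  tab1_season <- tab1[[season]][tab1$variable == "prokaryote_abundance_cells_ml"]
  dur <- SEASON_DURATION_H[[season]]
  experiment_design(
    season = season, total_dapi_t0 = tab1_season, duration_h = dur,
    sample_times_h = seq(0, dur, length.out = 4),
    replicates = replicates, noise = noise, seed = seed, D = D
  )
}

#' Simulate one seasonal microcosm experiment
#'
#' Generates a tidy abundance table for every group, treatment, replicate
#' bottle and sampling time, together with the generating truth. Each
#' group grows (or declines) exponentially in each treatment at the net
#' rate given by [true_net_rate()]; the DI and VR treatments start at a
#' fraction `D` of the ambient cells (dilution removes starting cells as
#' well as pressures). Expected abundance is
#' `N0 * start_dilution * exp(k_true * t / 24)` with `t` in hours, and
#' observed counts multiply in the design's noise model. Aerobic anoxygenic
#' phototrophs are enumerated only in the control and predator-reduced
#' bottles (the treatments with paired light/dark incubations) and at two
#' sampling times, mirroring the study design; all other groups are
#' sampled at every time in all six treatments.
#'
#' @param design An [experiment_design()].
#' @param groups Group specifications; defaults to
#'   [default_season_specs()] for the design's season.
#'
#' @return A list with `abundance` (tibble: `season`, `treatment`,
#'   `replicate`, `group`, `time_h`, `cells_per_ml`) and `truth` (list
#'   with the generating specs, per-group/treatment `k_true`, and each
#'   group's generating mortality partition). The same design (including
#'   its seed) always yields an identical table.
#' @export
make_experiment <- function(design,
                            groups = default_season_specs(design$season)) {
  stopifnot(inherits(design, "experiment_design"))
  check_group_specs(groups)
  codes <- treatment_codes(design$D)

  k_true <- tidyr::crossing(group = groups$name, code = codes$code)
  k_true <- dplyr::left_join(k_true, codes, by = "code")
  gidx <- match(k_true$group, groups$name)
  k_true$k_true <- groups$mu[gidx] *
    ifelse(k_true$light, groups$light_modifier[gidx], 1) -
    (k_true$grazer_factor * groups$m_g[gidx] +
       k_true$resource_factor * groups$r_c[gidx] +
       k_true$virus_factor * groups$m_v[gidx])

  # AAP: two time points, CT/PR bottles only
  aap_times <- range(design$sample_times_h)
  grid <- tidyr::crossing(
    group = groups$name, code = codes$code,
    replicate = paste0("R", seq_len(design$replicates)),
    time_h = design$sample_times_h
  )
  keep <- grid$group != "AAP" |
    (grid$code %in% c("CT_L", "CT_D", "PR_L", "PR_D") &
       grid$time_h %in% aap_times)
  grid <- grid[keep, ]

  grid <- dplyr::left_join(grid, k_true[c("group", "code", "k_true",
                                          "start_dilution")],
                           by = c("group", "code"))
  n0 <- groups$initial_fraction[match(grid$group, groups$name)] *
    design$total_dapi_t0
  expected <- n0 * grid$start_dilution * exp(grid$k_true * grid$time_h / 24)

  noise <- design$noise
  observed <- withr::with_seed(design$seed, {
    switch(noise$model,
      none      = expected,
      lognormal = {
        sdlog <- sqrt(log(1 + noise$cv^2))
        expected * stats::rlnorm(length(expected), meanlog = -sdlog^2 / 2,
                                 sdlog = sdlog)
      },
      poisson   = stats::rpois(length(expected),
                               expected * noise$count_scale) /
        noise$count_scale
    )
  })

  abundance <- tibble::tibble(
    season = design$season,
    treatment = grid$code,
    replicate = grid$replicate,
    group = grid$group,
    time_h = grid$time_h,
    cells_per_ml = observed
  )
  abundance <- dplyr::arrange(abundance, .data$treatment, .data$replicate,
                              .data$group, .data$time_h)

  partitions <- tibble::tibble(
    group = groups$name,
    mu_light = groups$mu * groups$light_modifier,
    mu = groups$mu, m_g = groups$m_g, r_c = groups$r_c, m_v = groups$m_v,
    D = design$D
  )

  list(
    abundance = abundance,
    truth = list(
      season = design$season, seed = design$seed, D = design$D,
      groups = groups,
      k_true = k_true[c("group", "code", "k_true")],
      partitions = partitions
    )
  )
}

#' Simulate all four seasonal experiments
#'
#' @param seed Integer base seed; each season uses `seed + offset` so the
#'   four experiments are independent but jointly reproducible.
#' @param noise A [noise_spec()].
#' @param seasons Seasons to simulate.
#' @return A list with the combined `abundance` tibble and a named list of
#'   per-season `truth` objects.
#' @export
simulate_seasons <- function(seed, noise = noise_spec(),
                             seasons = SEASON_LEVELS) {
  sims <- lapply(seq_along(seasons), function(i) {
    design <- default_season_design(seasons[i], seed = seed + i - 1L,
                                    noise = noise)
    make_experiment(design)
  })
  names(sims) <- seasons
  list(
    abundance = dplyr::bind_rows(lapply(sims, `[[`, "abundance")),
    truth = lapply(sims, `[[`, "truth")
  )
}
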