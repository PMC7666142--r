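test_that("true net rate applies pressure factors and the light modifier", {
  g <- group_spec("SAR11", 0.4, mu = 1.1, m_g = 0.4, r_c = 8 / 15,
                  m_v = 1 / 15)
  expect_equal(true_net_rate(g, "CT_L"), 0.1, tolerance = 1e-12)
  expect_equal(true_net_rate(g, "PR_L"), 0.5, tolerance = 1e-12)
  expect_equal(true_net_rate(g, "DI_L"), 0.8, tolerance = 1e-12)
  expect_equal(true_net_rate(g, "VR_L"), 0.85, tolerance = 1e-12)

  lossless <- group_spec("ALT", 0.1, mu = 2, m_g = 0, r_c = 0, m_v = 0)
  for (code in treatment_codes()$code) {
    expect_equal(true_net_rate(lossless, code), 2)
  }

  lit <- group_spec("AAP", 0.1, mu = 1, m_g = 0, r_c = 0, m_v = 0,
                    light_modifier = 1.2)
  expect_equal(true_net_rate(lit, "PR_L") / true_net_rate(lit, "PR_D"), 1.2)
})

test_that("default season specs match the packaged in situ tables", {
  winter <- default_season_specs("winter")
  expect_equal(winter$initial_fraction[winter$name == "SAR11"], 0.435)
  fall <- default_season_specs("fall")
  expect_equal(fall$initial_fraction[fall$name == "ALT"], 0.043)
  expect_error(default_season_specs("monsoon"), "arg")

  summer_design <- default_season_design("summer", seed = 1)
  expect_equal(summer_design$total_dapi_t0, 7.28e5)
  expect_equal(summer_design$duration_h, 36)
  expect_equal(default_season_design("spring", seed = 1)$duration_h, 48)
})

test_that("parent-group rates dominate nested children in every treatment", {
  codes <- treatment_codes()
  for (season in c("winter", "spring", "summer", "fall")) {
    specs <- default_season_specs(season)
    row <- function(name) specs[specs$name == name, ]
    for (i in seq_len(nrow(codes))) {
      tr <- codes[i, ]
      expect_gte(true_net_rate(row("GAMMA"), tr),
                 true_net_rate(row("ALT"), tr) - 1e-12)
      expect_gte(true_net_rate(row("GAMMA"), tr),
                 true_net_rate(row("NOR5"), tr) - 1e-12)
      for (child in c("ROSEO", "SAR11", "GAMMA", "CFB")) {
        expect_gte(true_net_rate(row("EUB"), tr),
                   true_net_rate(row(child), tr) - 1e-12)
      }
      expect_gte(true_net_rate(row("PRK"), tr),
                 true_net_rate(row("EUB"), tr) - 1e-12)
    }
  }
})

test_that("noiseless expected abundances follow the closed form", {
  design <- experiment_design("spring", total_dapi_t0 = 1e6,
                              duration_h = 48,
                              sample_times_h = c(0, 24, 48),
                              replicates = 1L, noise = noise_spec("none"),
                              seed = 1)
  g <- group_spec("SAR11", 0.4, mu = 0.5, m_g = 0, r_c = 0, m_v = 0)
  sim <- make_experiment(design, g)
  ct <- sim$abundance[sim$abundance$treatment == "CT_L", ]
  expect_equal(ct$cells_per_ml[ct$time_h == 24], 4e5 * exp(0.5),
               tolerance = 1e-12)
  # dilution reduces starting cells to D * N0
  di <- sim$abundance[sim$abundance$treatment == "DI_L", ]
  expect_equal(di$cells_per_ml[di$time_h == 0], 0.25 * 4e5)
})

test_that("simulation is reproducible from the seed alone", {
  d <- function() default_season_design("fall", seed = 123)
  s1 <- make_experiment(d())
  s2 <- make_experiment(d())
  expect_identical(s1$abundance, s2$abundance)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_abundance_csv(s1$abundance, f1)
  write_abundance_csv(s2$abundance, f2)
  expect_identical(readLines(f1), readLines(f2))

  s3 <- make_experiment(default_season_design("fall", seed = 124))
  expect_false(identical(s1$abundance$cells_per_ml,
                         s3$abundance$cells_per_ml))
})

test_that("probe nesting is conserved at every noiseless time point", {
  for (season in c("winter", "summer")) {
    design <- default_season_design(season, seed = 2,
                                    noise = noise_spec("none"))
    ab <- make_experiment(design)$abundance
    wide <- tidyr::pivot_wider(ab, names_from = "group",
                               values_from = "cells_per_ml")
    tol <- 1e-9
    expect_true(all(wide$ALT + wide$NOR5 <= wide$GAMMA * (1 + tol)))
    expect_true(all(wide$ROSEO + wide$SAR11 + wide$GAMMA + wide$CFB <=
                      wide$EUB * (1 + tol)))
    expect_true(all(wide$EUB <= wide$PRK * (1 + tol)))
  }
})

test_that("design validation rejects malformed sampling schemes", {
  expect_error(
    experiment_design("winter", 1e6, duration_h = 36,
                      sample_times_h = c(0, 12, 48), seed = 1),
    "within"
  )
  expect_error(
    experiment_design("winter", 1e6, sample_times_h = c(0, 24, 24),
                      seed = 1),
    "strictly increasing"
  )
  expect_error(
    experiment_design("winter", 1e6, sample_times_h = c(12, 24), seed = 1),
    "start at 0"
  )
  expect_error(experiment_design("winter", 1e6), "seed")
})

test_that("group nesting of initial fractions is validated", {
  bad <- dplyr::bind_rows(
    group_spec("GAMMA", 0.02, mu = 1, m_g = 0, r_c = 0, m_v = 0),
    group_spec("ALT", 0.03, mu = 1, m_g = 0, r_c = 0, m_v = 0),
    group_spec("NOR5", 0.01, mu = 1, m_g = 0, r_c = 0, m_v = 0)
  )
  design <- default_season_design("winter", seed = 1)
  expect_error(make_experiment(design, bad), "nesting")
})

test_that("AAP are enumerated twice and only in control/predator bottles", {
  ab <- make_experiment(default_season_design("winter", seed = 5))$abundance
  aap <- ab[ab$group == "AAP", ]
  expect_setequal(unique(aap$treatment), c("CT_L", "CT_D", "PR_L", "PR_D"))
  expect_setequal(unique(aap$time_h), c(0, 36))
  other <- ab[ab$group != "AAP", ]
  expect_setequal(unique(other$treatment), treatment_codes()$code)
  expect_equal(length(unique(other$time_h)), 4)
})

test_that("noise models perturb counts around the expected trajectory", {
  base <- default_season_design("spring", seed = 31,
                                noise = noise_spec("none"))
  clean <- make_experiment(base)$abundance
  noisy <- make_experiment(
    default_season_design("spring", seed = 31,
                          noise = noise_spec("lognormal", cv = 0.1))
  )$abundance
  ratio <- noisy$cells_per_ml / clean$cells_per_ml
  expect_true(all(ratio > 0))
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(sd(ratio), 0.1, tolerance = 0.25)

  pois <- make_experiment(
    default_season_design("spring", seed = 31,
                          noise = noise_spec("poisson", count_scale = 1e-3))
  )$abundance
  expect_true(all(pois$cells_per_ml * 1e-3 ==
                    round(pois$cells_per_ml * 1e-3)))
})
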