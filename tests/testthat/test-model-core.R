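test_that("forward model reproduces hand-computed treatment rates", {
  # zero losses: every treatment grows at mu
  expect_equal(
    unlist(predict_net_rates(0.5, 0, 0, 0)[c("k_ct", "k_pr", "k_di", "k_vr")]),
    c(k_ct = 0.5, k_pr = 0.5, k_di = 0.5, k_vr = 0.5)
  )
  # direct substitution into the four equations
  expect_equal(
    unlist(predict_net_rates(1.1, 0.4, 8 / 15, 1 / 15,
                             D = 0.25)[c("k_ct", "k_pr", "k_di", "k_vr")]),
    c(k_ct = 0.1, k_pr = 0.5, k_di = 0.8, k_vr = 0.85)
  )
  # grazing-only losses make the diluted and virus-reduced rates coincide
  expect_equal(
    unlist(predict_net_rates(1, 1, 0, 0, D = 0.25)[c("k_ct", "k_pr",
                                                     "k_di", "k_vr")]),
    c(k_ct = 0, k_pr = 1, k_di = 0.75, k_vr = 0.75)
  )
})

test_that("forward model rejects invalid inputs by name", {
  expect_error(predict_net_rates(NaN, 0, 0, 0), "mu")
  expect_error(predict_net_rates(1, Inf, 0, 0), "m_g")
  expect_error(predict_net_rates(1, 0, 0, 0, D = 1), "D")
})

test_that("closed-form solver inverts the forward model", {
  sol <- solve_partition(0.1, 0.5, 0.8, 0.85, D = 0.25)
  expect_equal(sol$mu, 1.1, tolerance = 1e-12)
  expect_equal(sol$m_g, 0.4, tolerance = 1e-12)
  expect_equal(sol$r_c, 8 / 15, tolerance = 1e-12)
  expect_equal(sol$m_v, 1 / 15, tolerance = 1e-12)

  # identical rates in all treatments force zero losses
  for (D in c(0.1, 0.25, 0.5)) {
    sol <- solve_partition(0.3, 0.3, 0.3, 0.3, D = D)
    expect_equal(unlist(sol[c("mu", "m_g", "r_c", "m_v")]),
                 c(mu = 0.3, m_g = 0, r_c = 0, m_v = 0))
  }

  sol <- solve_partition(0, 1, 0.75, 0.75, D = 0.25)
  expect_equal(unlist(sol[c("mu", "m_g", "r_c", "m_v")]),
               c(mu = 1, m_g = 1, r_c = 0, m_v = 0), tolerance = 1e-12)

  expect_error(solve_partition(0, 1, 0.75, 0.75, D = 1), "singular|between")
  expect_error(solve_partition(NA, 1, 0.75, 0.75), "k_ct")
})

test_that("solver round-trips the forward model over random parameters", {
  sets <- random_partition_sets(1000, seed = 42)
  for (D in unique(sets$D)) {
    sub <- sets[sets$D == D, ]
    k <- predict_net_rates(sub$mu, sub$m_g, sub$r_c, sub$m_v, D = D)
    sol <- solve_partition(k$k_ct, k$k_pr, k$k_di, k$k_vr, D = D)
    expect_lt(max(abs(sol$mu - sub$mu)), 1e-9)
    expect_lt(max(abs(sol$m_g - sub$m_g)), 1e-9)
    expect_lt(max(abs(sol$r_c - sub$r_c)), 1e-9)
    expect_lt(max(abs(sol$m_v - sub$m_v)), 1e-9)
  }
})

test_that("closed form agrees with a dense linear solve", {
  sets <- random_partition_sets(200, seed = 7)
  k <- mapply(function(mu, m_g, r_c, m_v, D) {
    unlist(predict_net_rates(mu, m_g, r_c, m_v, D))
  }, sets$mu, sets$m_g, sets$r_c, sets$m_v, sets$D)
  for (i in seq_len(nrow(sets))) {
    sol <- solve_partition(k["k_ct", i], k["k_pr", i], k["k_di", i],
                           k["k_vr", i], D = sets$D[i])
    oracle <- dense_solve_partition(k["k_ct", i], k["k_pr", i],
                                    k["k_di", i], k["k_vr", i],
                                    D = sets$D[i])
    expect_equal(unlist(sol[c("mu", "m_g", "r_c", "m_v")]), oracle,
                 tolerance = 1e-10)
  }
})

test_that("grazing mortality is exactly the PR - CT first difference", {
  sets <- random_partition_sets(100, seed = 3)
  k <- predict_net_rates(sets$mu, sets$m_g, sets$r_c, sets$m_v, D = 0.25)
  sol <- solve_partition(k$k_ct, k$k_pr, k$k_di, k$k_vr, D = 0.25)
  expect_identical(sol$m_g, k$k_pr - k$k_ct)
})

test_that("loss estimates respond monotonically to their treatment rate", {
  base <- c(k_ct = 0.1, k_pr = 0.5, k_di = 0.8, k_vr = 0.85)
  m_v <- sapply(seq(0.5, 1.5, by = 0.1), function(kvr) {
    solve_partition(base["k_ct"], base["k_pr"], base["k_di"], kvr)$m_v
  })
  expect_true(all(diff(m_v) > 0))
  m_g <- sapply(seq(0, 1, by = 0.1), function(kpr) {
    solve_partition(base["k_ct"], kpr, base["k_di"], base["k_vr"])$m_g
  })
  expect_true(all(diff(m_g) > 0))
})

test_that("negative components are flagged, and truncated only on request", {
  sol <- solve_partition(0.2, 0.1, 0.4, 0.3)  # k_pr < k_ct -> m_g < 0
  expect_lt(sol$m_g, 0)
  expect_match(sol$negative_components, "m_g")
  trunc <- solve_partition(0.2, 0.1, 0.4, 0.3, truncate_negative = TRUE)
  expect_identical(trunc$m_g, 0)
  expect_match(trunc$negative_components, "m_g") # flag records the algebra
})

test_that("response ratios follow the arithmetic and the epsilon policy", {
  expect_equal(response_ratio(0.5, 0.1, "grazing")$value, 5)
  # equal rates in both treatments sit on the 1:1 line
  expect_equal(response_ratio(0.3, 0.3, "light")$value, 1)
  deg <- response_ratio(0.3, -0.05, "resources")
  expect_true(is.na(deg$value))
  expect_equal(deg$difference, 0.35)
  expect_match(deg$reason, "epsilon")
  expect_error(response_ratio(1, 1, "grazing", epsilon = 0), "epsilon")
})

test_that("table-level ratios pair the right treatments", {
  means <- tibble::tibble(
    season = "winter", group = "SAR11",
    treatment = c("CT_L", "CT_D", "PR_L", "PR_D", "DI_L", "VR_L"),
    k_mean = c(0.2, 0.1, 0.4, 0.3, 0.8, 0.9)
  )
  rr <- response_ratios(means)
  get <- function(kind, num) {
    rr$value[rr$kind == kind & rr$num_treatment == num]
  }
  expect_equal(get("grazing", "PR_L"), 0.4 / 0.2)
  expect_equal(get("resources", "DI_L"), 0.8 / 0.4)
  expect_equal(get("viruses", "VR_L"), 0.9 / 0.8)
  expect_equal(get("light", "CT_L"), 2)
  expect_equal(get("light", "PR_L"), 0.4 / 0.3)
})

test_that("partitioning a rate table works on means and per replicate", {
  truth <- list(mu = 1.2, m_g = 0.5, r_c = 0.3, m_v = 0.1)
  k <- predict_net_rates(truth$mu, truth$m_g, truth$r_c, truth$m_v)
  reps <- tidyr::crossing(
    season = "spring", group = c("SAR11", "ALT"),
    replicate = c("R1", "R2", "R3"),
    tibble::tibble(treatment = c("CT_L", "PR_L", "DI_L", "VR_L"),
                   k = c(k$k_ct, k$k_pr, k$k_di, k$k_vr))
  )
  by_mean <- partition_rates(mean_rates(dplyr::mutate(reps, k = k)))
  expect_equal(by_mean$mu, rep(truth$mu, 2), tolerance = 1e-12)
  by_rep <- partition_rates(reps, per_replicate = TRUE)
  expect_equal(by_rep$mu_mean, rep(truth$mu, 2), tolerance = 1e-12)
  expect_equal(by_rep$m_g_sd, rep(0, 2))

  # missing treatment coverage is reported, not fatal
  gap <- partition_rates(mean_rates(reps[reps$treatment != "VR_L", ]))
  expect_false(any(gap$complete))
  expect_true(all(is.na(gap$mu)))
})

test_that("bootstrap partition is seeded and brackets the point estimate", {
  k <- predict_net_rates(1.0, 0.4, 0.2, 0.1)
  reps <- tidyr::crossing(
    season = "summer", group = "CFB", replicate = c("R1", "R2", "R3"),
    tibble::tibble(treatment = c("CT_L", "PR_L", "DI_L", "VR_L"),
                   k0 = c(k$k_ct, k$k_pr, k$k_di, k$k_vr))
  )
  reps$k <- reps$k0 + withr::with_seed(9, rnorm(nrow(reps), sd = 0.05))
  b1 <- bootstrap_partition(reps, n_boot = 99, seed = 5)
  b2 <- bootstrap_partition(reps, n_boot = 99, seed = 5)
  expect_identical(b1, b2)
  mu_row <- b1[b1$component == "mu", ]
  expect_gt(mu_row$upper, mu_row$lower)
  expect_true(mu_row$estimate > mu_row$lower - 0.5 &&
                mu_row$estimate < mu_row$upper + 0.5)
})
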