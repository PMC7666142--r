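# Independent oracles used across the suite. Each reimplements the
# quantity it checks by a generic route (dense linear algebra, exhaustive
# enumeration, the textbook recurrence) so agreement is informative.

# Generic dense solve of the four-treatment budget for (mu, m_g, r_c, m_v).
dense_solve_partition <- function(k_ct, k_pr, k_di, k_vr, D) {
  A <- rbind(
    c(1, -1, -1, -1),
    c(1,  0, -1, -1),
    c(1, -D, -D, -1),
    c(1, -D, -D, -D)
  )
  setNames(as.numeric(solve(A, c(k_ct, k_pr, k_di, k_vr))),
           c("mu", "m_g", "r_c", "m_v"))
}

random_partition_sets <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    mu  = runif(n, -1, 6),
    m_g = runif(n, -1, 6),
    r_c = runif(n, -1, 6),
    m_v = runif(n, -1, 6),
    D   = sample(c(0.1, 0.25, 0.5), n, replace = TRUE)
  ))
}

# Exhaustive all-windows scan using lm(), with the same tie-breaks the
# package documents (max r^2, then longer, then earlier start).
brute_force_best_window <- function(times_h, cells, min_points = 3L) {
  ord <- order(times_h)
  t <- times_h[ord]
  y <- log(cells[ord])
  n <- length(t)
  best <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len < min_points) next
      fit <- lm(y[i:j] ~ t[i:j])
      # suppress lm's perfect-fit warning: exact fits are the point here
      r2 <- if (len <= 2L) -1 else
        suppressWarnings(summary(fit)$r.squared)
      if (is.na(r2)) r2 <- -1
      cand <- list(i = i, j = j, len = len, r2 = r2,
                   slope = unname(coef(fit)[2]))
      better <- is.null(best) || cand$r2 > best$r2 + 1e-12 ||
        (abs(cand$r2 - best$r2) <= 1e-12 &&
           (cand$len > best$len ||
              (cand$len == best$len && cand$i < best$i)))
      if (better) best <- cand
    }
  }
  list(k = best$slope * 24, t_start_h = t[best$i], t_end_h = t[best$j])
}

# O(n^3) Lance-Williams agglomeration with Ward coefficients on squared
# Euclidean distances; returns the merge heights (criterion values) in
# order.
lw_ward_heights <- function(x) {
  d2 <- as.matrix(dist(x))^2
  n <- nrow(d2)
  active <- seq_len(n)
  size <- rep(1L, n)
  heights <- numeric(0)
  repeat {
    if (length(active) < 2L) break
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        i <- active[a]; j <- active[b]
        if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    for (k in setdiff(active, c(i, j))) {
      ni <- size[i]; nj <- size[j]; nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

toy_abundance <- function(k_per_day, n0 = 1e5, times = c(0, 12, 24, 36),
                          season = "winter", treatment = "CT_L",
                          replicate = "R1", group = "SAR11") {
  tibble::tibble(
    season = season, treatment = treatment, replicate = replicate,
    group = group, time_h = times,
    cells_per_ml = n0 * exp(k_per_day * times / 24)
  )
}
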