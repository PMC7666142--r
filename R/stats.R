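#' Overall rate range and spread per group
#'
#' Collapses per-experiment (min, max) growth-rate pairs into an overall
#' range per group: the minimum of minima, maximum of maxima and their
#' difference (the spread between the fastest and slowest rate ever
#' observed for that group). Given a single pre-computed overall range row
#' per group the spread is computed directly from it. Display rounding is
#' half-up to one decimal, matching how such summary tables are printed;
#' the unrounded spread is kept alongside.
#'
#' @param rate_ranges Tibble with columns `group`, `min_rate`, `max_rate`
#'   (day^-1) and optionally an experiment identifier; one row per group
#'   and experiment.
#' @return A tibble with one row per group: `min_rate`, `max_rate`,
#'   `spread`, `spread_rounded`.
#' @examples
#' range_summary(tibble::tibble(group = "ALT", min_rate = 0.1,
#'                              max_rate = 5.8))
#' @export
range_summary <- function(rate_ranges) {
  stopifnot(all(c("group", "min_rate", "max_rate") %in% names(rate_ranges)))
  bad <- which(rate_ranges$min_rate > rate_ranges$max_rate)
  if (length(bad)) {
    stop("min_rate exceeds max_rate in row ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(rate_ranges, .data$group),
    min_rate = min(.data$min_rate),
    max_rate = max(.data$max_rate),
    .groups = "drop"
  )
  out$spread <- out$max_rate - out$min_rate
  out$spread_rounded <- round_half_up(out$spread, 1L)
  out
}

#' Round half away from zero
#'
#' Commercial rounding (0.25 -> 0.3 at one decimal), as used for printed
#' rate tables; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Tests for differences in rates between groups of a single factor
#' (season, bacterioplankton group or treatment) and, when requested,
#' reports honest-significant-difference pairwise comparisons at level
#' `alpha`.
#'
#' @param values Numeric response (growth or mortality rates, day^-1).
#' @param labels Factor (or coercible) with >= 2 levels, each with >= 2
#'   observations.
#' @param alpha Significance level for the pairwise flags (default 0.05).
#' @return A list with `f_statistic`, `p_value`, `df`, and `tukey`, a
#'   tibble of pairwise differences with confidence bounds, adjusted p
#'   values and a `significant` flag.
#' @export
anova_tukey <- function(values, labels, alpha = 0.05) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(table(labels) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  check_finite(values, "values")
  dat <- data.frame(value = values, label = labels)
  fit <- stats::aov(value ~ label, data = dat)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$label
  tukey <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"], lower = tk[, "lwr"], upper = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  tukey$significant <- !is.na(tukey$p_adj) & tukey$p_adj < alpha
  list(
    f_statistic = tab[1, "F value"],
    p_value = tab[1, "Pr(>F)"],
    df = c(between = tab[1, "Df"], within = tab[2, "Df"]),
    alpha = alpha,
    tukey = tukey
  )
}

#' Ward hierarchical clustering of community samples
#'
#' Clusters samples (experiments, treatments, time points) by their group
#' abundance profiles with Ward's minimum-variance criterion, on either
#' Euclidean or Bray-Curtis dissimilarity (the usual choice for relative
#' abundance data).
#'
#' @param x Numeric samples-by-features matrix (or data frame) with row
#'   names identifying samples.
#' @param distance `"euclidean"` or `"bray"`.
#' @return An object of class `hclust`; merge heights are non-decreasing.
#' @seealso [dendrogram_text()] to serialise the tree.
#' @export
ward_cluster <- function(x, distance = c("euclidean", "bray")) {
  distance <- match.arg(distance)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(x))) {
    stop("non-finite feature values are not allowed", call. = FALSE)
  }
  d <- switch(distance,
    euclidean = stats::dist(x),
    bray = vegan::vegdist(x, method = "bray")
  )
  stats::hclust(d, method = "ward.D2")
}

#' Serialise a dendrogram as nested Newick-style text
#'
#' @param hc An `hclust` object.
#' @param digits Height precision.
#' @return A single string, e.g. `"((A:0,B:0):1.5,C:1.5);"`.
#' @export
dendrogram_text <- function(hc, digits = 6L) {
  stopifnot(inherits(hc, "hclust"))
  labels <- hc$labels %||% as.character(seq_along(hc$order))
  build <- function(i, parent_h) {
    if (i < 0) {
      paste0(labels[-i], ":", format(parent_h, digits = digits,
                                     trim = TRUE))
    } else {
      h <- hc$height[i]
      paste0("(", build(hc$merge[i, 1], h), ",",
             build(hc$merge[i, 2], h), "):",
             format(parent_h - h, digits = digits, trim = TRUE))
    }
  }
  n <- length(hc$height)
  top <- hc$height[n]
  paste0("(", build(hc$merge[n, 1], top), ",",
         build(hc$merge[n, 2], top), ");")
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity
#' matrix: the pseudo-F statistic from the partition of the squared
#' dissimilarities, with a permutation p value
#' `p = (number of permuted F >= observed + 1) / (n_perm + 1)` under free
#' permutation of the raw labels.
#'
#' @param d A `dist` object or square symmetric matrix of dissimilarities
#'   with zero diagonal.
#' @param labels Factor (or coercible) of group membership, one per
#'   sample; every level needs at least 2 members.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   results.
#' @return A list with `pseudo_f`, `p_value`, `r_squared`, `df` and
#'   `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12) ||
        any(abs(diag(m)) > 1e-12)) {
      stop("`d` must be a symmetric dissimilarity matrix with zero ",
           "diagonal", call. = FALSE)
    }
    d <- stats::as.dist(m)
  }
  labels <- factor(labels)
  if (nlevels(labels) < 2L || any(table(labels) < 2L)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  dat <- data.frame(label = labels)
  res <- withr::with_seed(seed,
    vegan::adonis2(d ~ label, data = dat, permutations = n_perm)
  )
  list(
    pseudo_f = res$F[1],
    p_value = res$`Pr(>F)`[1],
    r_squared = res$R2[1],
    df = c(between = res$Df[1], residual = res$Df[2]),
    n_perm = n_perm
  )
}
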