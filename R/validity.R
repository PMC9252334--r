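# The concurrent-validity statistical battery: D'Agostino-Pearson normality
# screen, right-tailed Spearman rank correlation with Bonferroni adjustment,
# Wilcoxon signed-rank paired comparison, step-count cutoff sweep, and
# direct difference metrics.

# --- moment helpers (columns of X are independent samples) ----------------
.col_moments <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  m2 <- colMeans(Xc^2)
  m3 <- colMeans(Xc^3)
  m4 <- colMeans(Xc^4)
  list(n = n, m2 = m2, g1 = m3 / m2^1.5, b2 = m4 / m2^2)
}

# D'Agostino (1970) normalizing transform of the sample skewness
.z_skew <- function(g1, n) {
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

# Anscombe-Glynn (1983) normalizing transform of the sample kurtosis
.z_kurt <- function(b2, n) {
  E <- 3 * (n - 1) / (n + 1)
  v <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - E) / sqrt(v)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xx * sqrt(2 / (A - 4))
  term2 <- sign(denom) * (abs((1 - 2 / A) / denom))^(1 / 3)
  ((1 - 2 / (9 * A)) - term2) / sqrt(2 / (9 * A))
}

.k2_matrix <- function(X) {
  mo <- .col_moments(X)
  z1 <- .z_skew(mo$g1, mo$n)
  z2 <- .z_kurt(mo$b2, mo$n)
  k2 <- z1^2 + z2^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalizing transforms of the sample skewness (D'Agostino
#' 1970) and kurtosis (Anscombe & Glynn 1983) into
#' `K2 = z_skew^2 + z_kurt^2`, referred to a chi-square distribution with
#' 2 degrees of freedom.  The test's asymptotics are unreliable below about
#' 20 observations, in which case a warning is emitted.
#'
#' @param x Numeric sample (n >= 8 required; n >= 20 recommended).
#' @return List with `statistic` (K2), `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations", call. = FALSE)
  if (n < 20L) warning("D'Agostino-Pearson test is unreliable for n < 20",
                       call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate sample: zero variance",
                               call. = FALSE)
  r <- .k2_matrix(matrix(x, ncol = 1))
  list(statistic = unname(r$k2), p = unname(r$p),
       z_skew = unname(r$z_skew), z_kurt = unname(r$z_kurt), n = n)
}

.permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- cbind(v[i], .permutations(v[-i]))
  do.call(rbind, out)
}

#' Right-tailed Spearman rank correlation
#'
#' Spearman's rho computed as the Pearson correlation of average ranks, with
#' a right-tailed p-value for the alternative `rho > 0`.  For `n <= 8` the
#' p-value is exact, by full enumeration of the `n!` pairings; above that it
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors, `n >= 4`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) uses exact for `n <= 8`.
#' @return List with `rho`, `p_right`, `n`, `method`.
#' @export
spearman_right <- function(x, y, exact = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_exact <- if (is.null(exact)) n <= 8L else isTRUE(exact)
  if (use_exact) {
    P <- .permutations(seq_len(n))
    ryp <- matrix(ry[P], nrow(P), n)
    s <- as.numeric(ryp %*% rx)
    rho_all <- (s / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(rho_all >= rho - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1 - 1e-15) {
      p <- if (rho > 0) 0 else 1
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
    }
    method <- "t approximation"
  }
  list(rho = rho, p_right = p, n = n, method = method)
}

#' Bonferroni adjustment
#'
#' @param p P-value(s).
#' @param factor Number of comparisons (>= 1).
#' @return `min(1, factor * p)`, elementwise.
#' @export
bonferroni_adjust <- function(p, factor) {
  stopifnot(factor >= 1)
  pmin(1, factor * p)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of a location difference between paired measurements
#' (e.g., the same gait feature in ON vs OFF treatment states).  Zero
#' differences are dropped; tied absolute differences receive average
#' ranks.  The p-value is exact (full enumeration of the `2^n` sign
#' patterns) for up to 12 effective pairs, and uses the normal
#' approximation with continuity and tie corrections above that.
#'
#' @param on_values,off_values Paired numeric vectors.
#' @return List with `W` (sum of positive-difference ranks), `p`,
#'   `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(on_values, off_values) {
  ok <- is.finite(on_values) & is.finite(off_values)
  d <- on_values[ok] - off_values[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate pairs: all differences zero", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wdist <- as.numeric(signs %*% r)
    p_ge <- mean(Wdist >= W - 1e-9)
    p_le <- mean(Wdist <= W + 1e-9)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(W = W, p = p, n_effective = n, method = method)
}

#' Step-count cutoff sweep
#'
#' For each candidate cap on the reference step count, fits an ordinary
#' least-squares regression of the video-detected step counts on the
#' reference counts over the bouts retained under that cap, and reports the
#' fit's R-squared and slope.  The shape of R-squared versus cutoff locates
#' the step-count regime where clustering-based detection stops tracking
#' the reference.
#'
#' @param video_counts,reference_counts Paired step counts per bout.
#' @param cutoffs Ascending vector of candidate caps.
#' @return Data frame with columns
#'   `cutoff, n, slope, intercept, r_squared`; cutoffs retaining fewer than
#'   3 bouts are skipped and listed in attribute `"skipped"`.
#' @export
cutoff_sweep <- function(video_counts, reference_counts, cutoffs) {
  ok <- is.finite(video_counts) & is.finite(reference_counts)
  v <- video_counts[ok]
  r <- reference_counts[ok]
  rows <- list()
  skipped <- numeric(0)
  for (cc in sort(cutoffs)) {
    keep <- r <= cc
    if (sum(keep) < 3L || stats::var(r[keep]) == 0) {
      skipped <- c(skipped, cc)
      next
    }
    fit <- stats::lm(v[keep] ~ r[keep])
    rows[[length(rows) + 1L]] <- data.frame(
      cutoff = cc, n = sum(keep),
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cutoff = numeric(0), n = integer(0), slope = numeric(0),
               intercept = numeric(0), r_squared = numeric(0))
  attr(out, "skipped") <- skipped
  out
}

#' Mean, mean absolute and percent difference
#'
#' Direct agreement metrics for feature pairs measured in the same units:
#' `mean(v - r)`, `mean(|v - r|)` and `100 * mean(|v - r| / r)` (the
#' percent term uses only pairs with a strictly positive reference value;
#' the number excluded is reported).
#'
#' @param video_values,reference_values Paired numeric vectors.
#' @return List with `mean_diff`, `mean_abs_diff`, `percent_diff`, `n`,
#'   `n_excluded_percent`.
#' @export
difference_metrics <- function(video_values, reference_values) {
  ok <- is.finite(video_values) & is.finite(reference_values)
  v <- video_values[ok]
  r <- reference_values[ok]
  pos <- r > 0
  list(
    mean_diff = mean(v - r),
    mean_abs_diff = mean(abs(v - r)),
    percent_diff = if (any(pos))
      100 * mean(abs(v[pos] - r[pos]) / r[pos]) else NA_real_,
    n = length(v),
    n_excluded_percent = sum(!pos)
  )
}

.default_pairing <- function(features, reference) {
  cand <- list(n_steps = "n_steps", cadence = "cadence",
               step_width_mean = "step_width_ratio_mean",
               step_width_cv = "step_width_cv",
               step_time_cv = "step_time_cv",
               step_length_mean = "step_length_mean",
               speed = "speed")
  keep <- vapply(names(cand), function(v)
    v %in% names(features) && cand[[v]] %in% names(reference), logical(1))
  cand[keep]
}

#' Concurrent-validity correlation report
#'
#' For every video/reference feature pair and every stratum (combination of
#' annotation method, estimator and walking direction present in the
#' features table), computes the right-tailed Spearman correlation between
#' the video feature and its reference counterpart over the bouts shared by
#' both tables, attaches the D'Agostino-Pearson normality p-values of both
#' sides, and Bonferroni-adjusts the p-values.
#'
#' @param features Per-bout video features: data frame with `bout_id`,
#'   stratum columns (`annotation_method`, `estimator`, `direction`, any of
#'   which may be absent) and feature columns.
#' @param reference Per-bout reference features keyed by `bout_id`.
#' @param pairing Named list mapping video feature columns to reference
#'   columns; defaults to the canonical pairing of the shared features.
#' @param factor Bonferroni factor.  Default `NULL` counts, for each
#'   reference feature, the number of correlations sharing it (e.g. 18 for
#'   a 3-estimator x 2-method x 2-direction 2D analysis, 6 for one 3D
#'   estimator).
#' @param min_n Minimum complete pairs per correlation (default 4).
#' @return Long-format data frame, one row per (pair, stratum): `pair`,
#'   stratum columns, `n`, `rho`, `p_right`, `p_adj`, `normality_p_video`,
#'   `normality_p_reference`, `bonferroni_factor`.
#' @export
validity_report <- function(features, reference, pairing = NULL,
                            factor = NULL, min_n = 4) {
  if (is.null(pairing)) pairing <- .default_pairing(features, reference)
  if (!length(pairing)) stop("no feature pairs to correlate", call. = FALSE)
  strat_cols <- intersect(c("annotation_method", "estimator", "direction"),
                          names(features))
  strata <- if (length(strat_cols)) {
    unique(features[strat_cols])
  } else {
    data.frame(row.names = 1)
  }
  ri <- match(features$bout_id, reference$bout_id)
  rows <- list()
  for (vfeat in names(pairing)) {
    rfeat <- pairing[[vfeat]]
    for (s in seq_len(nrow(strata))) {
      sel <- rep(TRUE, nrow(features))
      for (sc in strat_cols) sel <- sel & features[[sc]] == strata[s, sc]
      v <- features[[vfeat]][sel]
      r <- reference[[rfeat]][ri[sel]]
      ok <- is.finite(v) & is.finite(r)
      row <- data.frame(pair = paste0(vfeat, "<->", rfeat),
                        video_feature = vfeat, reference_feature = rfeat,
                        n = sum(ok), rho = NA_real_, p_right = NA_real_,
                        normality_p_video = NA_real_,
                        normality_p_reference = NA_real_)
      for (sc in strat_cols) row[[sc]] <- strata[s, sc]
      if (sum(ok) >= max(4, min_n)) {
        sp <- tryCatch(spearman_right(v[ok], r[ok]), error = function(e) NULL)
        if (!is.null(sp)) {
          row$rho <- sp$rho
          row$p_right <- sp$p_right
        }
        row$normality_p_video <- tryCatch(
          suppressWarnings(dagostino_pearson(v[ok])$p),
          error = function(e) NA_real_)
        row$normality_p_reference <- tryCatch(
          suppressWarnings(dagostino_pearson(r[ok])$p),
          error = function(e) NA_real_)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(factor)) {
    shared <- table(out$reference_feature)
    out$bonferroni_factor <- as.numeric(shared[out$reference_feature])
  } else {
    out$bonferroni_factor <- factor
  }
  out$p_adj <- bonferroni_adjust(out$p_right, pmax(out$bonferroni_factor, 1))
  rownames(out) <- NULL
  out
}
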