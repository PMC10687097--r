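#' Mann-Kendall trend test
#'
#' Nonparametric trend test on an annual series:
#' `S = sum_{i<j} sgn(x_j - x_i)`, with tie-corrected variance
#' `Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18` (sum over tied
#' groups of size t), normal deviate `Z = (S -+ 1)/sqrt(Var(S))` with
#' continuity correction (0 when `S = 0`), tie-corrected rank correlation
#' tau-b, and a two-sided normal p-value. The normal approximation is
#' adequate for the 20-year series this package targets.
#'
#' @param x Numeric series, length >= 4, finite.
#' @return Object of class `mk_test`: list with `S`, `var_S`, `Z`, `tau`,
#'   `p`, `n`.
#' @examples
#' mann_kendall(1:20)   # S = 190, tau = 1
#' @export
mann_kendall <- function(x) {
  n <- length(x)
  if (n < 4) stop("Mann-Kendall test needs n >= 4")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  d <- sign(outer(x, x, "-"))       # d[i, j] = sgn(x_i - x_j)
  S <- sum(d[lower.tri(d)])         # pairs i > j, i.e. later minus earlier
  ties <- table(x)
  t <- as.numeric(ties[ties > 1])
  var_S <- (n * (n - 1) * (2 * n + 5) - sum(t * (t - 1) * (2 * t + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(var_S)
       else if (S < 0) (S + 1) / sqrt(var_S)
       else 0
  D <- n * (n - 1) / 2
  tie_term <- sum(t * (t - 1) / 2)
  denom <- sqrt((D - tie_term) * D)   # time index has no ties
  tau <- if (denom > 0) S / denom else 0
  p <- if (var_S > 0) 2 * stats::pnorm(-abs(Z)) else 1
  structure(list(S = S, var_S = var_S, Z = Z, tau = tau, p = p, n = n),
            class = "mk_test")
}

#' @export
print.mk_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Kendall: n = %d, S = %g, tau = %.4f, Z = %.3f, p = %.4g\n",
    x$n, x$S, x$tau, x$Z, x$p))
  invisible(x)
}

#' Sen's slope
#'
#' Median of all pairwise slopes `(x_j - x_i)/(t_j - t_i)`, a robust trend
#' magnitude estimator (head/km^2 per year for annual density series).
#' Pairs with duplicate times are excluded.
#'
#' @param x Numeric series (n >= 2).
#' @param times Observation times (default `1:n`).
#' @return The median pairwise slope.
#' @examples
#' sens_slope(3 + 2 * (1:10))  # exactly 2
#' @export
sens_slope <- function(x, times = seq_along(x)) {
  n <- length(x)
  if (n < 2) stop("Sen's slope needs n >= 2")
  if (length(times) != n) stop("times must match the series length")
  ij <- utils::combn(n, 2)
  dt <- times[ij[2, ]] - times[ij[1, ]]
  keep <- dt != 0
  if (!any(keep)) stop("all time pairs are duplicates")
  stats::median((x[ij[2, keep]] - x[ij[1, keep]]) / dt[keep])
}

#' Per-pixel trend surface over an annual stack
#'
#' Runs [mann_kendall()] and [sens_slope()] on every pixel's annual series
#' and masks pixels significant at `alpha` (raw p-values by default; set
#' `fdr = TRUE` for a Benjamini-Hochberg-adjusted mask). Pixels with any
#' missing year are skipped.
#'
#' @param stack List of [density_surface()]s (or matrices) in year order,
#'   length >= 4, identical geometries.
#' @param times Observation times (default `1:length(stack)`).
#' @param alpha Significance level for the mask (default 0.05).
#' @param fdr Apply BH false-discovery-rate correction before masking.
#' @return Object of class `trend_surface`: matrices `tau`, `slope`, `p`,
#'   logical `mask`, plus `alpha` and `n_years`.
#' @export
trend_surface <- function(stack, times = seq_along(stack), alpha = 0.05,
                          fdr = FALSE) {
  if (length(stack) < 4) stop("trend analysis needs >= 4 years")
  mats <- lapply(stack, surface_values)
  geoms <- Filter(Negate(is.null),
                  lapply(stack, function(s)
                    if (inherits(s, "density_surface")) s$geometry else NULL))
  if (length(geoms) > 1)
    for (g in geoms[-1]) if (!same_geometry(geoms[[1]], g))
      stop("stack geometries are inconsistent")
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("stack geometries are inconsistent")

  nr <- dims[1, 1]; nc <- dims[2, 1]
  Y <- vapply(mats, as.vector, numeric(nr * nc))  # pixels x years
  ok <- rowSums(!is.finite(Y)) == 0
  tau <- slope <- p <- rep(NA_real_, nr * nc)
  idx <- which(ok)
  if (length(idx)) {
    n <- length(mats)
    ij <- utils::combn(n, 2)
    V <- Y[idx, , drop = FALSE]
    D1 <- V[, ij[2, ], drop = FALSE] - V[, ij[1, ], drop = FALSE]
    S <- rowSums(sign(D1))
    dt <- times[ij[2, ]] - times[ij[1, ]]
    keep <- dt != 0
    if (!any(keep)) stop("all time pairs are duplicates")
    slope[idx] <- apply(sweep(D1[, keep, drop = FALSE], 2, dt[keep], "/"),
                        1, stats::median)
    # fast path for pixels without value ties; exact tie handling otherwise
    tied <- rowSums(D1 == 0) > 0
    D <- n * (n - 1) / 2
    var0 <- n * (n - 1) * (2 * n + 5) / 18
    Z <- ifelse(S > 0, (S - 1) / sqrt(var0),
                ifelse(S < 0, (S + 1) / sqrt(var0), 0))
    tau[idx] <- S / D
    p[idx] <- 2 * stats::pnorm(-abs(Z))
    for (k in which(tied)) {
      mk <- mann_kendall(V[k, ])
      tau[idx[k]] <- mk$tau
      p[idx[k]] <- mk$p
    }
  }
  if (fdr) p[idx] <- stats::p.adjust(p[idx], method = "BH")
  mask <- matrix(p < alpha, nr, nc)
  structure(
    list(tau = matrix(tau, nr, nc), slope = matrix(slope, nr, nc),
         p = matrix(p, nr, nc), mask = mask,
         alpha = alpha, n_years = length(stack)),
    class = "trend_surface"
  )
}

#' @export
print.trend_surface <- function(x, ...) {
  valid <- !is.na(x$p)
  cat(sprintf(
    "<trend_surface> %d-year stack, %d valid px; %.1f%% significant at p < %g\n",
    x$n_years, sum(valid), 100 * mean(x$mask[valid]), x$alpha))
  cat(sprintf("  tau in [%.3f, %.3f], Sen slope in [%.4f, %.4f]\n",
              min(x$tau, na.rm = TRUE), max(x$tau, na.rm = TRUE),
              min(x$slope, na.rm = TRUE), max(x$slope, na.rm = TRUE)))
  invisible(x)
}
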