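#' Hill-Weir expectation of r2 under mutation-drift-recombination
#'
#' Sample-size-adjusted expectation of `r2` between two sites separated by a
#' population recombination parameter `C = Gamma * d` (`Gamma = 4Nc` per bp,
#' `d` the distance), for `n` sampled gametes:
#'
#' `E[r2] = (10+C) / ((2+C)(11+C)) * [1 + (3+C)(12+12C+C^2) /
#'          (n (2+C)(11+C)(13+C))]`
#'
#' At `C = 0` the large-`n` limit is `10/22`; the curve decreases towards 0
#' as `C` grows.
#'
#' @param C population recombination parameter(s), `>= 0`.
#' @param n number of lines compared (`>= 2`).
#' @return expected r2, vectorised over `C`.
#' @export
hill_weir_expectation <- function(C, n) {
  if (any(C < 0)) stopf("C must be >= 0")
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2")
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) /
       (n * (2 + C) * (11 + C) * (13 + C)))
}

#' Fit the LD decay curve (nonlinear least squares for Gamma)
#'
#' Minimises `sum(r2 - E[r2 | gamma * d, n])^2` over `gamma >= 0` (per bp),
#' using `nls` (port algorithm) from multiple deterministic starts with a
#' grid-plus-golden-section fallback; the best SSE wins, so the fit is
#' deterministic given the data.
#'
#' @param scatter data.frame with columns `distance` (bp, > 0) and `r2`, at
#'   least 5 rows.
#' @param n number of lines compared.
#' @param starts starting values for gamma per bp.
#' @return `decay_fit` list: `gamma_per_bp`, `n`, `sse`, `n_points`,
#'   `boundary` (`TRUE` when the optimum sits in the large-gamma regime where
#'   the curve is effectively flat over the observed distances).
#' @export
fit_gamma <- function(scatter, n, starts = c(1e-4, 1e-2, 1)) {
  stopifnot(is.data.frame(scatter),
            all(c("distance", "r2") %in% names(scatter)))
  d <- scatter$distance; r2 <- scatter$r2
  if (length(d) < 5L) stopf("need at least 5 points")
  if (any(d <= 0)) stopf("distances must be > 0")
  if (length(unique(d)) == 1L) stopf("degenerate scatter: all distances equal")
  sse_of <- function(g) sum((r2 - hill_weir_expectation(g * d, n))^2)
  best <- list(gamma = NA_real_, sse = Inf)
  consider <- function(g) {
    if (is.finite(g) && g >= 0) {
      s <- sse_of(g)
      if (s < best$sse) best <<- list(gamma = g, sse = s)
    }
  }
  for (g0 in starts) {
    fit <- tryCatch(suppressWarnings(
      stats::nls(r2 ~ hill_weir_expectation(gamma * d, n),
                 data = data.frame(d = d, r2 = r2),
                 start = list(gamma = g0), lower = list(gamma = 0),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                              warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) consider(stats::coef(fit)[["gamma"]])
  }
  # deterministic fallback/refinement: log-grid + local golden-section
  grid <- 10^seq(-7, 2, by = 0.25)
  gs <- vapply(grid, sse_of, numeric(1))
  g_best <- grid[which.min(gs)]
  opt <- stats::optimize(sse_of, c(g_best / 10, g_best * 10), tol = 1e-12)
  consider(opt$minimum)
  consider(g_best)
  curve_range <- hill_weir_expectation(best$gamma * range(d), n)
  # large-gamma regime: the fitted curve has already decayed (essentially)
  # to its asymptote before the first observed distance, so gamma is only
  # bounded below by the data
  structure(list(gamma_per_bp = best$gamma, n = n, sse = best$sse,
                 n_points = length(d),
                 boundary = curve_range[1L] < 0.05 ||
                   abs(diff(curve_range)) < 1e-4),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit: gamma = %.4g /bp, n = %d, SSE = %.4g over %d points%s\n",
              x$gamma_per_bp, x$n, x$sse, x$n_points,
              if (isTRUE(x$boundary)) " [flat/boundary regime]" else ""))
  invisible(x)
}

#' Empirical LD-significance threshold from unlinked loci
#'
#' Square-root transforms the unlinked-marker r2 values (bringing them closer
#' to normality), takes the 95th percentile (type-7 linear interpolation),
#' and squares it back. Values above the threshold are unlikely without
#' linkage.
#'
#' @param unlinked_r2 r2 values from pairs of unlinked loci (>= 20 values in
#'   `[0, 1]`).
#' @param percentile percentile on the square-root scale (default 95).
#' @return threshold r2.
#' @export
ld_threshold <- function(unlinked_r2, percentile = 95) {
  unlinked_r2 <- unlinked_r2[!is.na(unlinked_r2)]
  if (length(unlinked_r2) < 20L) stopf("need >= 20 unlinked r2 values")
  if (any(unlinked_r2 < 0 | unlinked_r2 > 1)) stopf("r2 values outside [0, 1]")
  stats::quantile(sqrt(unlinked_r2), percentile / 100, type = 7,
                  names = FALSE)^2
}

#' Extent of linkage disequilibrium
#'
#' Distance at which the fitted decay curve `E[r2 | gamma * d, n]` crosses
#' the significance threshold, found by root bisection to 0.5 bp. If the
#' curve is already below the threshold as `d -> 0+`, the extent is 0
#' (status `"zero"`); if it is still above at `d_max`, the crossing lies
#' beyond the analysed range (status `"beyond_range"`).
#'
#' @param fit a `decay_fit` from [fit_gamma()].
#' @param threshold_r2 threshold from [ld_threshold()].
#' @param d_max largest distance considered, in bp (default 1371, the longest
#'   analysed fragment).
#' @return list with `extent_bp` (0, the crossing, or `NA`) and `status`
#'   (`"ok"`, `"zero"`, `"beyond_range"`).
#' @export
ld_extent <- function(fit, threshold_r2, d_max = 1371) {
  stopifnot(inherits(fit, "decay_fit"), is_prob(threshold_r2), d_max > 0)
  g <- fit$gamma_per_bp
  f <- function(d) hill_weir_expectation(g * d, fit$n) - threshold_r2
  if (f(1e-9) <= 0) return(list(extent_bp = 0, status = "zero"))
  if (f(d_max) > 0) return(list(extent_bp = NA_real_, status = "beyond_range"))
  root <- stats::uniroot(f, c(1e-9, d_max), tol = 0.25)
  list(extent_bp = root$root, status = "ok")
}

#' Analytic extent from a known gamma
#'
#' Convenience inversion of the Hill-Weir curve for a known recombination
#' intensity (used to benchmark the pipeline against simulation truth).
#'
#' @param gamma_per_bp recombination intensity per bp.
#' @param n sample size.
#' @param threshold_r2 threshold r2.
#' @param d_max search range in bp.
#' @return extent in bp (0 or `NA` sentinels as in [ld_extent()]).
#' @export
analytic_extent <- function(gamma_per_bp, n, threshold_r2, d_max = 1e6) {
  fit <- structure(list(gamma_per_bp = gamma_per_bp, n = as.integer(n),
                        sse = 0, n_points = 0L, boundary = FALSE),
                   class = "decay_fit")
  ld_extent(fit, threshold_r2, d_max = d_max)$extent_bp
}
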