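#' Parametric semivariogram model
#'
#' Isotropic semivariogram \eqn{\gamma(h)} with the three classic families.
#' All satisfy \eqn{\gamma(0) = 0}, are nondecreasing in lag, and approach
#' `nugget + psill` (the total sill) at large lag. `range_m` is the range
#' parameter of each family's standard form:
#' \describe{
#'   \item{spherical}{\eqn{\gamma(h) = n + s(1.5 h/a - 0.5 (h/a)^3)} for
#'     \eqn{h \le a}, \eqn{n + s} beyond — reaches the sill exactly at `a`.}
#'   \item{exponential}{\eqn{\gamma(h) = n + s(1 - e^{-h/a})} — `a` is the
#'     correlation length; the effective range is about `3 a`.}
#'   \item{gaussian}{\eqn{\gamma(h) = n + s(1 - e^{-(h/a)^2})}.}
#' }
#'
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget micro-scale variance at zero-plus lag (>= 0).
#' @param psill partial sill (>= 0); total sill is `nugget + psill`.
#' @param range_m range parameter in meters (> 0).
#' @return an object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range_m) {
  family <- match.arg(family)
  if (!is.finite(nugget) || nugget < 0) stop("variogram_model: nugget must be >= 0")
  if (!is.finite(psill) || psill < 0) stop("variogram_model: psill must be >= 0")
  if (!is.finite(range_m) || range_m <= 0) stop("variogram_model: range_m must be > 0")
  structure(list(family = family, nugget = as.numeric(nugget),
                 psill = as.numeric(psill), range_m = as.numeric(range_m)),
            class = "variogram_model")
}

#' Evaluate a semivariogram model at lag distances
#'
#' @param vm a [variogram_model()].
#' @param h numeric vector of lag distances (m, >= 0).
#' @return semivariances, with \eqn{\gamma(0) = 0} exactly.
#' @export
semivariance <- function(vm, h) {
  stopifnot(inherits(vm, "variogram_model"))
  a <- vm$range_m
  g <- switch(vm$family,
    spherical = {
      r <- pmin(h / a, 1)
      vm$psill * (1.5 * r - 0.5 * r^3)
    },
    exponential = vm$psill * (1 - exp(-h / a)),
    gaussian = vm$psill * (1 - exp(-(h / a)^2)))
  out <- vm$nugget + g
  out[h == 0] <- 0
  out
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$family, x$nugget, x$psill, x$range_m))
  if (!is.null(attr(x, "fit")))
    cat(sprintf("  fitted: weighted SSE %.4g over %d lag bins\n",
                attr(x, "fit")$wsse, attr(x, "fit")$n_bins))
  invisible(x)
}

#' @export
plot.variogram_model <- function(x, max_dist = NULL, ...) {
  emp <- attr(x, "empirical")
  if (is.null(max_dist))
    max_dist <- if (!is.null(emp)) max(emp$lag) * 1.05 else 2 * x$range_m
  h <- seq(0, max_dist, length.out = 200)
  graphics::plot(h, semivariance(x, h), type = "l", xlab = "lag (m)",
                 ylab = expression(gamma(h)),
                 main = sprintf("%s variogram", x$family), ...)
  if (!is.null(emp))
    graphics::points(emp$lag, emp$gamma, pch = 16,
                     cex = 0.6 + sqrt(emp$n_pairs / max(emp$n_pairs)))
  invisible(x)
}

#' Empirical (method-of-moments) semivariogram
#'
#' Bins point pairs by separation distance and computes, per bin,
#' \eqn{\hat\gamma(h) = \frac{1}{2 N(h)} \sum (z_i - z_j)^2} over the
#' \eqn{N(h)} pairs whose distance falls in the bin. Empty bins are
#' dropped.
#'
#' @param x,y point coordinates (m); all locations must be distinct.
#' @param values observed values at the points.
#' @param n_lags number of equal-width lag bins up to `max_dist`.
#' @param max_dist largest pair distance considered; default half the
#'   maximum pairwise distance (the conventional cutoff beyond which bins
#'   are dominated by few, geometry-driven pairs).
#' @return an object of class `empirical_variogram`: a data frame with
#'   columns `lag` (bin center of mass), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(x, y, values, n_lags = 12L,
                                max_dist = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n)
  if (n < 2L) stop("empirical_variogram: need at least 2 points")
  d <- as.vector(stats::dist(cbind(x, y)))
  if (any(d == 0))
    stop("empirical_variogram: duplicate point locations", call. = FALSE)
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (!is.finite(max_dist) || max_dist <= 0)
    stop("empirical_variogram: max_dist must be > 0")
  sq <- as.vector(stats::dist(matrix(values)))^2
  keep <- d <= max_dist
  d <- d[keep]; sq <- sq[keep]
  bin <- pmin(pmax(ceiling(d / (max_dist / n_lags)), 1L), n_lags)
  gamma <- tapply(sq, bin, function(s) sum(s) / (2 * length(s)))
  lag <- tapply(d, bin, mean)
  n_pairs <- tapply(d, bin, length)
  out <- data.frame(lag = as.numeric(lag), gamma = as.numeric(gamma),
                    n_pairs = as.integer(n_pairs))
  out <- out[order(out$lag), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf("empirical variogram: %d lag bins, %d pairs\n",
              nrow(x), sum(x$n_pairs)))
  print.data.frame(x, ...)
  invisible(x)
}

# weighted least squares for (nugget, psill) at a fixed range: the model is
# linear in those two once the family shape f(h; a) in [0, 1] is fixed
wls_nugget_sill <- function(f, gamma, w) {
  # minimize sum w (n + s f - gamma)^2 subject to n, s >= 0
  X <- cbind(1, f)
  A <- crossprod(X * sqrt(w))
  b <- crossprod(X, w * gamma)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(sol) && all(sol >= 0)) return(c(sol))
  # boundary cases
  s0 <- max(0, sum(w * f * gamma) / max(sum(w * f^2), .Machine$double.eps))
  n0 <- max(0, sum(w * gamma) / sum(w))
  cand <- list(c(0, s0), c(n0, 0))
  sse <- vapply(cand, function(p) sum(w * (p[1] + p[2] * f - gamma)^2), 0)
  cand[[which.min(sse)]]
}

#' Fit a semivariogram model to an empirical variogram
#'
#' Weighted least squares with pair-count weights \eqn{N(h)}: parameters
#' minimize \eqn{\sum_h N(h) (\gamma(h; \theta) - \hat\gamma(h))^2} subject
#' to `nugget, psill >= 0`, `range_m > 0`. The fit is deterministic: a
#' fixed grid of candidate ranges spanning the lag axis is scanned (nugget
#' and sill solved in closed form at each, since the model is linear in
#' them), and the best candidate is polished with bounded
#' quasi-Newton refinement.
#'
#' @param emp an [empirical_variogram()] with at least 3 retained bins.
#' @param family model family, default `"spherical"`.
#' @return a [variogram_model()] carrying the empirical variogram and fit
#'   diagnostics as attributes.
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential",
                                          "gaussian")) {
  stopifnot(inherits(emp, "empirical_variogram"))
  family <- match.arg(family)
  if (nrow(emp) < 3L)
    stop("fit_variogram: need at least 3 lag bins", call. = FALSE)
  h <- emp$lag; gam <- emp$gamma; w <- as.numeric(emp$n_pairs)
  shape <- function(a) {
    vm <- variogram_model(family, 0, 1, a)
    semivariance(vm, h)
  }
  ranges <- exp(seq(log(min(h) / 2), log(max(h) * 3), length.out = 40L))
  best <- NULL
  for (a in ranges) {
    ns <- wls_nugget_sill(shape(a), gam, w)
    sse <- sum(w * (ns[1] + ns[2] * shape(a) - gam)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(nugget = ns[1], psill = ns[2], range = a, sse = sse)
  }
  obj <- function(p) sum(w * (p[1] + p[2] * shape(p[3]) - gam)^2)
  opt <- tryCatch(
    stats::optim(c(best$nugget, best$psill, best$range), obj,
                 method = "L-BFGS-B",
                 lower = c(0, 0, min(h) / 100),
                 upper = c(Inf, Inf, max(h) * 100)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value))
    stop(sprintf(
      "fit_variogram: fit failed to converge (family %s, %d bins, start SSE %.4g)",
      family, nrow(emp), best$sse), call. = FALSE)
  p <- if (opt$value <= best$sse) opt$par else
    c(best$nugget, best$psill, best$range)
  vm <- variogram_model(family, p[1], p[2], max(p[3], .Machine$double.eps))
  attr(vm, "empirical") <- emp
  attr(vm, "fit") <- list(wsse = min(opt$value, best$sse), n_bins = nrow(emp),
                          converged = TRUE)
  vm
}
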