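#' Matern variogram model
#'
#' Container for the four parameters of an (isotropic) Matern semivariogram:
#' nugget \eqn{\tau^2}, partial sill \eqn{\sigma^2}, range \eqn{\phi} (same
#' units as the lag distances, metres throughout this package) and smoothness
#' \eqn{\kappa}.
#'
#' @param nugget Nugget variance, >= 0.
#' @param psill Partial sill, >= 0.
#' @param range Range parameter (m), > 0.
#' @param kappa Smoothness, > 0. `kappa = 0.5` is the exponential model.
#' @return An object of class `matern_variogram`.
#' @export
matern_variogram <- function(nugget, psill, range, kappa = 0.5) {
  stopifnot(is.numeric(nugget), is.numeric(psill), is.numeric(range),
            is.numeric(kappa), length(nugget) == 1L, length(psill) == 1L,
            length(range) == 1L, length(kappa) == 1L)
  if (nugget < 0) stop("nugget must be >= 0")
  if (psill < 0) stop("partial sill must be >= 0")
  if (range <= 0) stop("range must be > 0")
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(nugget = nugget, psill = psill, range = range,
                 kappa = kappa),
            class = "matern_variogram")
}

#' @export
print.matern_variogram <- function(x, ...) {
  cat(sprintf(
    "Matern variogram: nugget=%.4g psill=%.4g range=%.4g m kappa=%.3g\n",
    x$nugget, x$psill, x$range, x$kappa))
  invisible(x)
}

#' Matern correlation function
#'
#' \eqn{\rho(h) = 2^{1-\kappa}/\Gamma(\kappa) (h/\phi)^\kappa
#' K_\kappa(h/\phi)} with \eqn{\rho(0) = 1}; \eqn{K_\kappa} is the modified
#' Bessel function of the second kind.
#'
#' @param h Distances, >= 0.
#' @param range Range parameter \eqn{\phi} > 0.
#' @param kappa Smoothness \eqn{\kappa} > 0.
#' @return Correlations in (0, 1].
#' @export
matern_correlation <- function(h, range, kappa = 0.5) {
  if (any(h < 0)) stop("distances must be >= 0")
  if (range <= 0 || kappa <= 0) stop("invalid Matern parameters")
  u <- h / range
  out <- numeric(length(h))
  pos <- u > 0
  up <- u[pos]
  # besselK underflows for large arguments; the correlation is 0 there anyway
  rho <- (2^(1 - kappa) / gamma(kappa)) * up^kappa * besselK(up, kappa)
  rho[!is.finite(rho)] <- 0
  out[pos] <- pmin(rho, 1)
  out[!pos] <- 1
  out
}

#' Matern semivariance
#'
#' \eqn{\gamma(h) = \tau^2 + \sigma^2 (1 - \rho(h))} for h > 0 and
#' \eqn{\gamma(0) = 0}.
#'
#' @param h Distances (m), >= 0.
#' @param model A [matern_variogram()].
#' @return Semivariances of the same length as `h`.
#' @export
matern_semivariance <- function(h, model) {
  if (!inherits(model, "matern_variogram")) {
    stop("`model` must be a matern_variogram")
  }
  if (any(h < 0)) stop("distances must be >= 0")
  g <- model$nugget +
    model$psill * (1 - matern_correlation(h, model$range, model$kappa))
  g[h == 0] <- 0
  g
}

#' Matern covariance matrix at a set of distances
#'
#' Stationary covariance implied by the variogram:
#' \eqn{C(h) = \sigma^2 \rho(h)} for h > 0 and \eqn{C(0) = \sigma^2 +
#' \tau^2} (the nugget sits on the diagonal only).
#'
#' @param d Distance matrix (m).
#' @param model A [matern_variogram()].
#' @return Covariance matrix of the same dimension as `d`.
#' @export
matern_cov <- function(d, model) {
  if (!inherits(model, "matern_variogram")) {
    stop("`model` must be a matern_variogram")
  }
  C <- model$psill * matern_correlation(as.vector(d), model$range, model$kappa)
  C <- matrix(C, nrow(d), ncol(d))
  C[d == 0] <- C[d == 0] + model$nugget
  C
}
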