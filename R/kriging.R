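#' Ordinary kriging in rank (normal-score) space
#'
#' Solves the ordinary-kriging system (covariance form, unbiasedness
#' constraint: weights sum to 1) for each target location, using all data
#' (global neighborhood; the sampling designs this package addresses have a
#' few hundred sites).
#'
#' @param coords n x 2 matrix of data coordinates (m).
#' @param z Data values (typically normal scores), length n.
#' @param model A [matern_variogram()].
#' @param targets m x 2 matrix of prediction locations.
#' @return A data.frame of class `kriged_surface`: `x`, `y`, `estimate`
#'   (rank-space prediction) and `variance` (kriging variance, >= 0).
#' @export
ordinary_krige <- function(coords, z, model, targets) {
  coords <- as.matrix(coords)
  targets <- as.matrix(targets)
  n <- nrow(coords)
  if (length(z) != n) stop("coords and z must be aligned")
  dd <- as.matrix(stats::dist(coords))
  if (any(dd[upper.tri(dd)] == 0)) {
    stop("duplicate coordinates: kriging system is singular")
  }
  C <- matern_cov(dd, model)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  # cross-covariances data -> targets; nugget contributes only at h = 0
  dx <- outer(coords[, 1], targets[, 1], "-")
  dy <- outer(coords[, 2], targets[, 2], "-")
  d0 <- sqrt(dx^2 + dy^2)
  c0 <- model$psill * matern_correlation(as.vector(d0), model$range,
                                         model$kappa)
  c0 <- matrix(c0, n, nrow(targets))
  c0[d0 == 0] <- c0[d0 == 0] + model$nugget
  rhs <- rbind(c0, 1)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    stop("singular ordinary-kriging system: ", conditionMessage(e))
  })
  w <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1L, ]
  est <- unname(drop(crossprod(w, z)))
  sill0 <- model$psill + model$nugget
  vr <- unname(pmax(sill0 - colSums(w * c0) - mu, 0))
  out <- data.frame(x = targets[, 1], y = targets[, 2],
                    estimate = est, variance = vr)
  attr(out, "weight_sums") <- colSums(w)
  class(out) <- c("kriged_surface", "data.frame")
  out
}

#' Leave-one-out cross-validation of a kriging model
#'
#' For each site, predicts its (rank-space) value by ordinary kriging from
#' all other sites and forms the standardized squared error
#' \eqn{\theta_i = (z_i - \hat z_{-i})^2 / s^2_{-i}}. Under a correctly
#' specified model the \eqn{\theta_i} follow a chi-square distribution with
#' one degree of freedom, so their mean (Theta-mean, a.k.a. MSPE) should be
#' near 1 and their median (Theta-med, MedianSPE) near
#' `qchisq(0.5, 1) = 0.455`.
#'
#' Uses the bordered-inverse identity for ordinary kriging (one factorization
#' for all n leave-one-out systems); tests verify it against brute-force
#' refits.
#'
#' @param coords n x 2 coordinate matrix (n >= 10).
#' @param z Rank-space data values.
#' @param model A [matern_variogram()].
#' @param mean_envelope Half-width of the validity envelope around 1 for
#'   Theta-mean (default 0.1).
#' @param med_envelope Half-width of the envelope around 0.455 for Theta-med
#'   (default 0.12).
#' @return A list of class `cv_report`: `theta`, `theta_mean`, `theta_med`,
#'   `mspe`, `median_spe` (synonyms of the two above), `predicted`,
#'   `cv_variance`, `valid`.
#' @export
loo_crossvalidate <- function(coords, z, model,
                              mean_envelope = 0.1, med_envelope = 0.12) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 10L) stop("need at least 10 sites for leave-one-out validation")
  if (length(z) != n) stop("coords and z must be aligned")
  dd <- as.matrix(stats::dist(coords))
  dup <- which(dd == 0 & upper.tri(dd), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    stop("duplicate coordinates at sites ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  }
  C <- matern_cov(dd, model)
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e))
  })
  B <- Ainv[seq_len(n), seq_len(n), drop = FALSE]
  bd <- unname(diag(B))
  err <- unname(drop(B %*% z)) / bd    # z_i - zhat_{-i}
  s2 <- 1 / bd                         # LOO ordinary-kriging variance
  if (any(s2 <= 0)) stop("non-positive leave-one-out variance: bad model")
  theta <- err^2 / s2
  tm <- mean(theta)
  tmed <- stats::median(theta)
  target_med <- stats::qchisq(0.5, df = 1)
  structure(list(theta = theta,
                 theta_mean = tm,
                 theta_med = tmed,
                 mspe = tm,
                 median_spe = tmed,
                 predicted = z - err,
                 cv_variance = s2,
                 valid = abs(tm - 1) <= mean_envelope &&
                   abs(tmed - target_med) <= med_envelope),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOO cross-validation: Theta-mean = %.4f, Theta-med = %.4f (%s)\n",
              x$theta_mean, x$theta_med,
              if (x$valid) "valid" else "NOT valid"))
  invisible(x)
}

#' Significance stars
#'
#' Convention used throughout the campaign-comparison tables:
#' `"."` for p < 0.1, `"*"` < 0.05, `"**"` < 0.01, `"***"` < 0.001,
#' otherwise `"NS"`.
#'
#' @param p A p-value.
#' @return A character scalar.
#' @export
significance_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "." else "NS"
}

#' Paired Wilcoxon signed-rank comparison of two campaigns
#'
#' Zero differences are dropped; the exact null distribution is used for
#' n <= 25 non-zero untied differences, and the normal approximation with
#' tie correction otherwise.
#'
#' @param x_first,x_second Paired numeric vectors (site-matched values from
#'   the two sampling campaigns).
#' @return A list: `statistic` (V), `p_value`, `stars`, `n_used`, `method`.
#' @export
paired_wilcoxon <- function(x_first, x_second) {
  if (length(x_first) != length(x_second)) stop("vectors must be paired")
  ok <- is.finite(x_first) & is.finite(x_second)
  d <- x_second[ok] - x_first[ok]
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, stars = "NS",
                n_used = 0L, method = "all differences zero"))
  }
  if (length(d) < 3L) stop("fewer than 3 non-zero differences")
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       stars = significance_stars(wt$p.value),
       n_used = length(d),
       method = if (exact) "exact" else "normal approximation")
}
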