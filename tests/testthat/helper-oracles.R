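# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever the point is to cross-check them.

# Gaussian random field draw with exponential/Matern covariance, written
# directly from the closed forms.
grf_draw <- function(coords, psill = 1, range = 150, nugget = 0,
                     kappa = 0.5, jitter = 1e-10) {
  d <- as.matrix(stats::dist(coords))
  if (kappa == 0.5) {
    C <- psill * exp(-d / range)
  } else {
    u <- d / range
    C <- matrix(0, nrow(d), ncol(d))
    pos <- u > 0
    C[pos] <- psill * (2^(1 - kappa) / gamma(kappa)) *
      u[pos]^kappa * besselK(u[pos], kappa)
    C[!pos] <- psill
  }
  diag(C) <- psill + nugget
  unname(drop(crossprod(chol(C + diag(jitter, nrow(d))),
                        rnorm(nrow(d)))))
}

# Brute-force leave-one-out ordinary kriging: refit the full system for
# every held-out site.
bf_loo_ok <- function(coords, z, model) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  C <- model$psill * matern_correlation(as.vector(d), model$range,
                                        model$kappa)
  C <- matrix(C, n, n)
  diag(C) <- model$psill + model$nugget
  pred <- vr <- numeric(n)
  for (i in seq_len(n)) {
    Ci <- C[-i, -i]
    c0 <- C[-i, i]
    A <- rbind(cbind(Ci, 1), c(rep(1, n - 1), 0))
    sol <- solve(A, c(c0, 1))
    w <- sol[seq_len(n - 1)]
    pred[i] <- sum(w * z[-i])
    vr[i] <- model$psill + model$nugget - sum(w * c0) - sol[n]
  }
  list(pred = pred, var = vr)
}

# Total effects by exhaustive enumeration of every directed path in a DAG
# (sum over paths of the product of coefficients along the path).
enum_total_effects <- function(B) {
  K <- nrow(B)
  total <- matrix(0, K, K, dimnames = dimnames(B))
  walk <- function(node, target, prod) {
    out <- 0
    for (nxt in seq_len(K)) {
      if (B[node, nxt] != 0) {
        p <- prod * B[node, nxt]
        if (nxt == target) out <- out + p
        out <- out + walk(nxt, target, p)
      }
    }
    out
  }
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      total[i, j] <- walk(i, j, 1)
    }
  }
  total
}

# Exact two-sided p-value of the Wilcoxon signed-rank test by enumerating
# all 2^n sign assignments (no ties, no zeros).
enum_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(seq_len(2^n) - 1L, function(mask) {
    sum(r[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L])
  }, numeric(1))
  p <- 2 * min(mean(vs <= v_obs), mean(vs >= v_obs))
  min(p, 1)
}

# Minimal two-latent-variable data set with a planted standardized effect:
# y = beta x + sqrt(1 - beta^2) noise, both emitted as single MVs.
planted_two_block <- function(n, beta, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- beta * x + sqrt(1 - beta^2) * rnorm(n)
  data.frame(x = x, y = y)
}

two_block_spec <- function() {
  plspm_spec(list(plspm_block("X", "x"), plspm_block("Y", "y")),
             data.frame(from = "X", to = "Y"))
}
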