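#' Define a reflective measurement block
#'
#' One latent variable (LV) measured by one or more manifest variables
#' (MVs), mode A (reflective): outer weights are correlations between the
#' MVs and the inner estimate. The anchor MV fixes the LV's sign (its
#' loading is forced positive).
#'
#' @param lv LV name.
#' @param mvs Character vector of MV (column) names.
#' @param anchor MV anchoring the sign (default: first MV).
#' @return A list of class `plspm_block`.
#' @export
plspm_block <- function(lv, mvs, anchor = mvs[1]) {
  stopifnot(is.character(lv), length(lv) == 1L, length(mvs) >= 1L)
  if (!anchor %in% mvs) stop("anchor must be one of the block's MVs")
  structure(list(lv = lv, mvs = mvs, anchor = anchor),
            class = "plspm_block")
}

#' Define a PLS path model
#'
#' @param blocks List of [plspm_block()]s.
#' @param paths Either a two-column data.frame (`from`, `to`) of directed
#'   arrows, or a square named adjacency matrix over the LV names
#'   (`paths[from, to] != 0`). Must be acyclic.
#' @param scheme Inner weighting scheme: "centroid" (default), "factorial"
#'   or "path".
#' @param tol Convergence threshold on the outer weights.
#' @param max_iter Maximum number of iterations.
#' @return A list of class `plspm_spec`.
#' @export
plspm_spec <- function(blocks, paths, scheme = c("centroid", "factorial",
                                                 "path"),
                       tol = 1e-7, max_iter = 300L) {
  scheme <- match.arg(scheme)
  if (!all(vapply(blocks, inherits, logical(1), "plspm_block"))) {
    stop("blocks must be plspm_block objects")
  }
  lv <- vapply(blocks, `[[`, character(1), "lv")
  if (anyDuplicated(lv)) stop("duplicate LV names")
  names(blocks) <- lv
  if (is.data.frame(paths)) {
    A <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
    for (r in seq_len(nrow(paths))) {
      f <- as.character(paths$from[r])
      t <- as.character(paths$to[r])
      if (!f %in% lv || !t %in% lv) {
        stop(sprintf("path %s -> %s references an unknown LV", f, t))
      }
      A[f, t] <- 1
    }
  } else {
    A <- (paths[lv, lv, drop = FALSE] != 0) * 1
  }
  topological_order(A)  # errors on cycles
  endo <- colnames(A)[colSums(A) > 0]
  structure(list(blocks = blocks, adjacency = A, scheme = scheme,
                 tol = tol, max_iter = as.integer(max_iter),
                 lvs = lv, endogenous = endo),
            class = "plspm_spec")
}

#' Unidimensionality diagnostics of a reflective block
#'
#' Cronbach's alpha on standardized MVs and Dillon-Goldstein's rho from
#' the first principal axis; the block passes when both exceed 0.7.
#' Single-MV blocks pass trivially (alpha = rho = 1).
#'
#' @param block_data data.frame or matrix of the block's MVs.
#' @return List: `alpha`, `rho`, `pass`.
#' @export
unidimensionality <- function(block_data) {
  X <- as.matrix(block_data)
  p <- ncol(X)
  if (p == 1L) return(list(alpha = 1, rho = 1, pass = TRUE))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance MV in block")
  Xs <- scale(X)
  total <- rowSums(Xs)
  alpha <- (p / (p - 1)) * (1 - sum(apply(Xs, 2, stats::var)) /
                              stats::var(total))
  R <- stats::cor(X)
  ev <- eigen(R, symmetric = TRUE)
  lam <- ev$vectors[, 1] * sqrt(ev$values[1])
  if (sum(lam) < 0) lam <- -lam
  rho <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
  list(alpha = alpha, rho = rho, pass = alpha > 0.7 && rho > 0.7)
}

inner_weights <- function(Y, A, scheme) {
  # neighbor matrix: connected in either direction
  nb <- (A + t(A)) > 0
  E <- matrix(0, ncol(Y), ncol(Y), dimnames = dimnames(A))
  R <- stats::cor(Y)
  for (j in seq_len(ncol(Y))) {
    if (scheme == "centroid") {
      E[nb[, j], j] <- sign(R[nb[, j], j])
    } else if (scheme == "factorial") {
      E[nb[, j], j] <- R[nb[, j], j]
    } else { # path scheme
      preds <- A[, j] > 0
      succ <- nb[, j] & !preds
      if (any(preds)) {
        cf <- stats::lm.fit(cbind(1, Y[, preds, drop = FALSE]),
                            Y[, j])$coefficients[-1]
        E[preds, j] <- cf
      }
      E[succ, j] <- R[succ, j]
    }
  }
  E
}

#' Fit a PLS path model (mode A)
#'
#' Standardizes the MVs, initializes equal outer weights, and iterates
#' inner estimation (centroid/factorial/path scheme), mode-A outer weight
#' update (weights proportional to MV-inner-estimate correlations) and LV
#' rescoring until the outer weights stabilize. Then computes loadings,
#' cross-loadings, OLS path coefficients per endogenous LV, R-squared,
#' communalities and the goodness of fit. LV signs are anchored so each LV
#' correlates positively with its anchor MV. Rows with missing MVs are
#' dropped (count reported in the fit).
#'
#' @param data data.frame holding every MV column.
#' @param spec A [plspm_spec()].
#' @return A list of class `plspm_fit`: `scores` (unit-variance LV scores),
#'   `outer_weights`, `loadings`, `cross_loadings`, `path` (coefficient
#'   matrix from x to), `path_table`, `r2`, `communality`,
#'   `block_communality`, `gof`, `unidim`, `iterations`, `converged`,
#'   `n_used`, `n_dropped`, `spec`, `data`.
#' @export
fit_plspm <- function(data, spec) {
  if (!inherits(spec, "plspm_spec")) stop("`spec` must be a plspm_spec")
  mv_all <- unlist(lapply(spec$blocks, `[[`, "mvs"), use.names = FALSE)
  missing_cols <- setdiff(mv_all, names(data))
  if (length(missing_cols) > 0) {
    stop("MV column(s) absent from data: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data[, mv_all, drop = FALSE]
  ok <- stats::complete.cases(df)
  n_dropped <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  n <- nrow(df)
  if (n < 10L) stop("fewer than 10 complete rows")
  X <- scale(as.matrix(df))
  if (any(!is.finite(X))) stop("zero-variance MV")
  A <- spec$adjacency
  lvs <- spec$lvs
  blocks <- spec$blocks

  idx <- lapply(blocks, function(b) match(b$mvs, colnames(X)))
  w <- lapply(blocks, function(b) rep(1, length(b$mvs)))
  score_of <- function(w) {
    Y <- sapply(seq_along(blocks), function(j) {
      y <- X[, idx[[j]], drop = FALSE] %*% w[[j]]
      drop(y) / stats::sd(y)
    })
    colnames(Y) <- lvs
    # anchor sign
    for (j in seq_along(blocks)) {
      a <- match(blocks[[j]]$anchor, colnames(X))
      if (stats::cor(Y[, j], X[, a]) < 0) Y[, j] <- -Y[, j]
    }
    scale(Y, center = TRUE, scale = FALSE)
  }
  Y <- score_of(w)
  unit <- function(v) v / sqrt(sum(v^2))
  converged <- FALSE
  iter <- 0L
  while (iter < spec$max_iter) {
    iter <- iter + 1L
    E <- inner_weights(Y, A, spec$scheme)
    w_new <- vector("list", length(blocks))
    for (j in seq_along(blocks)) {
      z <- Y %*% E[, j]
      if (stats::sd(z) == 0) {
        stop(sprintf("inner estimate degenerate for LV '%s'", lvs[j]))
      }
      w_new[[j]] <- drop(stats::cor(X[, idx[[j]], drop = FALSE], z))
    }
    Y_new <- score_of(w_new)
    delta <- max(mapply(function(a, b) max(abs(unit(a) - unit(b))),
                        w, w_new))
    w <- w_new
    Y <- Y_new
    if (delta < spec$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("PLS algorithm did not converge in %d iterations",
                 spec$max_iter))
  }
  names(w) <- lvs

  cross <- stats::cor(X, Y)               # MV x LV
  loadings <- stats::setNames(numeric(length(mv_all)), colnames(X))
  for (j in seq_along(blocks)) {
    loadings[idx[[j]]] <- cross[idx[[j]], j]
  }
  communality <- loadings^2
  block_comm <- vapply(seq_along(blocks), function(j) {
    mean(communality[idx[[j]]])
  }, numeric(1))
  names(block_comm) <- lvs

  P <- matrix(0, length(lvs), length(lvs), dimnames = list(lvs, lvs))
  r2 <- stats::setNames(rep(NA_real_, length(lvs)), lvs)
  for (j in spec$endogenous) {
    preds <- lvs[A[, j] > 0]
    Xp <- Y[, preds, drop = FALSE]
    if (qr(Xp)$rank < ncol(Xp)) {
      stop(sprintf("collinear predecessors of LV '%s'", j))
    }
    fitj <- stats::lm.fit(cbind(`(Intercept)` = 1, Xp), Y[, j])
    P[preds, j] <- fitj$coefficients[-1]
    r2[j] <- 1 - sum(fitj$residuals^2) / sum((Y[, j] - mean(Y[, j]))^2)
  }

  unidim <- lapply(lvs, function(l) {
    unidimensionality(df[, blocks[[l]]$mvs, drop = FALSE])
  })
  names(unidim) <- lvs

  mean_comm <- mean(communality)
  mean_r2 <- mean(r2[spec$endogenous])
  fit <- list(scores = Y, outer_weights = w, loadings = loadings,
              cross_loadings = cross, path = P,
              path_table = path_table(P),
              r2 = r2, communality = communality,
              block_communality = block_comm,
              gof = sqrt(mean_comm * mean_r2),
              unidim = unidim,
              iterations = iter, converged = converged,
              n_used = n, n_dropped = n_dropped,
              spec = spec, data = df)
  class(fit) <- "plspm_fit"
  fit
}

path_table <- function(P) {
  nz <- which(P != 0, arr.ind = TRUE)
  data.frame(from = rownames(P)[nz[, 1]], to = colnames(P)[nz[, 2]],
             estimate = P[nz], stringsAsFactors = FALSE)
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("PLS path model: %d LVs, n = %d, %d iterations, GOF = %.3f\n",
              length(x$spec$lvs), x$n_used, x$iterations, x$gof))
  r2 <- x$r2[!is.na(x$r2)]
  cat("  R2:", paste(sprintf("%s = %.3f", names(r2), r2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Goodness of fit of a PLS path model
#'
#' GOF = sqrt(mean MV communality x mean R-squared over endogenous LVs),
#' labelled "correct" when strictly greater than 0.4 and "very good" when
#' strictly greater than 0.7.
#'
#' @param fit A [fit_plspm()] result.
#' @return List: `gof`, `label`, `mean_communality`, `mean_r2`.
#' @export
gof <- function(fit) {
  if (!inherits(fit, "plspm_fit")) stop("`fit` must be a plspm_fit")
  mc <- mean(fit$communality)
  mr <- mean(fit$r2[fit$spec$endogenous])
  g <- sqrt(mc * mr)
  list(gof = g,
       label = if (g > 0.7) "very good" else if (g > 0.4) "correct"
       else "poor",
       mean_communality = mc, mean_r2 = mr)
}

#' Direct, indirect and total effects from a path-coefficient matrix
#'
#' For an acyclic path matrix B (from x to), direct = B, total =
#' \eqn{\sum_{k=1}^{K} B^k} (exact for DAGs with K latent variables),
#' indirect = total - direct.
#'
#' @param B Square named path-coefficient matrix; must be nilpotent.
#' @return List: `direct`, `indirect`, `total` (matrices) and `table`
#'   (rows for every LV pair with a non-zero total effect).
#' @export
effects_decomposition <- function(B) {
  stopifnot(is.matrix(B), nrow(B) == ncol(B))
  K <- nrow(B)
  Bk <- B
  total <- B
  for (k in 2:max(K, 2)) {
    Bk <- Bk %*% B
    total <- total + Bk
  }
  if (any(abs(Bk %*% B) > 1e-12)) {
    stop("path matrix is not nilpotent (the model has a cycle)")
  }
  indirect <- total - B
  nz <- which(abs(total) > 0, arr.ind = TRUE)
  tab <- data.frame(from = rownames(B)[nz[, 1]],
                    to = colnames(B)[nz[, 2]],
                    direct = B[nz], indirect = indirect[nz],
                    total = total[nz], stringsAsFactors = FALSE)
  list(direct = B, indirect = indirect, total = total,
       table = tab[order(tab$to, tab$from), ])
}
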