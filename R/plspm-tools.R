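#' Measurement-model violations
#'
#' Flags every MV whose loading on its own LV is non-positive, or whose
#' cross-loading on a foreign LV exceeds its own-LV loading.
#'
#' @param fit A [fit_plspm()] result.
#' @return data.frame of violations: `mv`, `lv`, `type`, `severity`
#'   (larger = worse); zero rows when the measurement model is clean.
#' @export
validate_measurement <- function(fit) {
  if (!inherits(fit, "plspm_fit")) stop("`fit` must be a plspm_fit")
  out <- list()
  for (lvn in fit$spec$lvs) {
    for (mv in fit$spec$blocks[[lvn]]$mvs) {
      own <- fit$cross_loadings[mv, lvn]
      if (own <= 0) {
        out[[length(out) + 1L]] <- data.frame(
          mv = mv, lv = lvn, type = "non-positive loading",
          severity = -own, stringsAsFactors = FALSE)
        next
      }
      foreign <- fit$cross_loadings[mv, setdiff(fit$spec$lvs, lvn)]
      worst <- max(abs(foreign)) - own
      if (worst > 0) {
        out[[length(out) + 1L]] <- data.frame(
          mv = mv, lv = lvn, type = "higher foreign cross-loading",
          severity = worst, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mv = character(0), lv = character(0),
                      type = character(0), severity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

lv_base <- function(x) sub("_[0-9]{4}$", "", x)

drop_mv_from_spec <- function(spec, mv, lv) {
  blocks <- spec$blocks
  removed <- character(0)
  # symmetric removal: the counterpart MV (same base name) in the paired
  # campaign block is excluded too, mirroring "for both years"
  targets <- list(c(mv, lv))
  for (other in spec$lvs) {
    if (other != lv && lv_base(other) == lv_base(lv)) {
      cand <- blocks[[other]]$mvs[lv_base(blocks[[other]]$mvs) ==
                                    lv_base(mv)]
      for (cm in cand) targets[[length(targets) + 1L]] <- c(cm, other)
    }
  }
  for (tg in targets) {
    b <- blocks[[tg[2]]]
    if (!tg[1] %in% b$mvs) next
    left <- setdiff(b$mvs, tg[1])
    if (length(left) == 0L) {
      blocks[[tg[2]]] <- NULL
    } else {
      anchor <- if (b$anchor %in% left) b$anchor else left[1]
      blocks[[tg[2]]] <- plspm_block(b$lv, left, anchor)
    }
    removed <- c(removed, paste(tg[1], "from", tg[2]))
  }
  kept_lvs <- vapply(blocks, `[[`, character(1), "lv")
  lost_lvs <- setdiff(spec$lvs, kept_lvs)
  if (any(lost_lvs %in% spec$endogenous)) {
    stop(sprintf("pruning would empty endogenous LV '%s'",
                 intersect(lost_lvs, spec$endogenous)[1]))
  }
  A <- spec$adjacency[kept_lvs, kept_lvs, drop = FALSE]
  list(spec = plspm_spec(unname(blocks), A, scheme = spec$scheme,
                         tol = spec$tol, max_iter = spec$max_iter),
       removed = removed)
}

#' Iteratively prune a PLS path model
#'
#' Refits and removes the worst measurement violation (non-positive
#' loading, dominated cross-loading, or the weakest MV of a block failing
#' the unidimensionality criterion) one MV at a time until the model is
#' clean. Removals are applied symmetrically to the paired campaign block
#' (an MV dropped from a `*_2011` block is dropped from its `*_2016`
#' counterpart and vice versa). LVs emptied by pruning are removed; an
#' endogenous LV emptying is an error.
#'
#' @param data data.frame with the MV columns.
#' @param spec A [plspm_spec()].
#' @param max_steps Safety cap on pruning iterations.
#' @return List: `spec` (reduced), `fit` (final clean fit), `audit`
#'   (data.frame of removals with reasons).
#' @export
prune_model <- function(data, spec, max_steps = 50L) {
  audit <- list()
  for (step in seq_len(max_steps)) {
    fit <- fit_plspm(data, spec)
    viol <- validate_measurement(fit)
    for (lvn in fit$spec$lvs) {
      ud <- fit$unidim[[lvn]]
      if (!ud$pass) {
        mvs <- fit$spec$blocks[[lvn]]$mvs
        weakest <- mvs[which.min(fit$loadings[mvs])]
        viol <- rbind(viol, data.frame(
          mv = weakest, lv = lvn, type = "block not unidimensional",
          severity = 0.7 - min(ud$alpha, ud$rho),
          stringsAsFactors = FALSE))
      }
    }
    if (nrow(viol) == 0L) {
      return(list(spec = spec, fit = fit,
                  audit = if (length(audit)) do.call(rbind, audit)
                  else data.frame()))
    }
    worst <- viol[which.max(viol$severity), ]
    dropped <- drop_mv_from_spec(spec, worst$mv, worst$lv)
    spec <- dropped$spec
    audit[[length(audit) + 1L]] <- data.frame(
      step = step, mv = worst$mv, lv = worst$lv, type = worst$type,
      removed = paste(dropped$removed, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  stop("pruning did not reach a clean model within max_steps")
}

#' Bootstrap validation of the path coefficients
#'
#' Resamples rows with replacement, refits the model, and summarizes each
#' path coefficient with its bootstrap standard error, percentile
#' confidence interval and t statistic (estimate / bootstrap SE against a
#' standard normal reference). A path is flagged accurate iff its CI
#' excludes 0 and |t| exceeds the normal critical value. LV signs stay
#' aligned with the full-data fit through the anchor-MV rule.
#'
#' @param data data.frame with the MV columns.
#' @param spec A [plspm_spec()].
#' @param n_boot Number of bootstrap resamples (the reference analysis
#'   uses 10,000; smaller values are fine for checks).
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return A list of class `bootstrap_report`: `table` (per path: estimate,
#'   boot SE, CI bounds, t, accurate), `n_boot`, `n_failed`, `seed`.
#' @export
bootstrap_validate <- function(data, spec, n_boot = 10000L, seed = 1,
                               conf = 0.95) {
  full <- fit_plspm(data, spec)
  pt <- full$path_table
  if (nrow(pt) == 0L) stop("model has no paths to validate")
  set.seed(seed)
  n <- nrow(full$data)
  draws <- matrix(NA_real_, n_boot, nrow(pt))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(fit_plspm(full$data[rows, , drop = FALSE], spec),
                   error = function(e) NULL)
    if (is.null(fb)) {
      failed <- failed + 1L
      next
    }
    draws[b, ] <- fb$path[cbind(pt$from, pt$to)]
  }
  if (failed > 0.05 * n_boot) {
    stop(sprintf("%d of %d bootstrap refits failed (> 5%%)", failed,
                 n_boot))
  }
  alpha <- (1 - conf) / 2
  se <- apply(draws, 2, stats::sd, na.rm = TRUE)
  lo <- apply(draws, 2, stats::quantile, probs = alpha, na.rm = TRUE)
  hi <- apply(draws, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  tstat <- pt$estimate / se
  crit <- stats::qnorm(1 - alpha)
  tab <- data.frame(from = pt$from, to = pt$to, estimate = pt$estimate,
                    boot_se = se, ci_lower = lo, ci_upper = hi,
                    t = tstat,
                    accurate = (lo > 0 | hi < 0) & abs(tstat) > crit,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, n_boot = n_boot, n_failed = failed,
                 seed = seed, conf = conf),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("Bootstrap validation (%d resamples, %d failed):\n",
              x$n_boot, x$n_failed))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

terminal_lvs <- function(spec) {
  A <- spec$adjacency
  cand <- spec$lvs[rowSums(A) == 0 & colSums(A) > 0]
  if (length(cand) == 0L) spec$endogenous else cand
}

predict_response_rmse <- function(data, spec, k = 5, seed = 1) {
  set.seed(seed)
  mv_all <- unlist(lapply(spec$blocks, `[[`, "mvs"), use.names = FALSE)
  df <- data[stats::complete.cases(data[, mv_all, drop = FALSE]),
             mv_all, drop = FALSE]
  n <- nrow(df)
  fold <- sample(rep_len(seq_len(k), n))
  resp <- terminal_lvs(spec)
  ord <- topological_order(spec$adjacency)
  errs <- c()
  for (f in seq_len(k)) {
    train <- df[fold != f, , drop = FALSE]
    test <- df[fold == f, , drop = FALSE]
    ft <- fit_plspm(train, spec)
    mu <- colMeans(train)
    sg <- apply(train, 2, stats::sd)
    Z <- sweep(sweep(as.matrix(test), 2, mu), 2, sg, "/")
    sc <- matrix(NA_real_, nrow(test), length(spec$lvs),
                 dimnames = list(NULL, spec$lvs))
    for (lvn in ord) {
      preds <- spec$lvs[spec$adjacency[, lvn] > 0]
      if (lvn %in% resp && length(preds) > 0) {
        sc[, lvn] <- sc[, preds, drop = FALSE] %*% ft$path[preds, lvn]
      } else {
        b <- spec$blocks[[lvn]]
        w <- ft$outer_weights[[lvn]]
        y <- Z[, b$mvs, drop = FALSE] %*% w
        # scale as the training scores were scaled
        ytr <- scale(as.matrix(train[, b$mvs, drop = FALSE])) %*% w
        sc[, lvn] <- (y - mean(ytr)) / stats::sd(ytr) *
          sign(stats::cor(ytr, scale(train[[b$anchor]]))[1])
      }
    }
    for (lvn in resp) {
      for (mv in spec$blocks[[lvn]]$mvs) {
        pred_mv <- ft$loadings[mv] * sc[, lvn]
        errs <- c(errs, (Z[, mv] - pred_mv)^2)
      }
    }
  }
  sqrt(mean(errs))
}

#' Compare candidate model architectures
#'
#' Fits each candidate spec and reports the R-squared of the terminal
#' response LV(s), the GOF, and the k-fold out-of-sample RMSE of the
#' response MVs predicted from the exogenous MVs through the fitted model.
#' Candidates are ranked by mean rank over the three criteria (higher R2,
#' higher GOF, lower prediction error). Candidates that fail to fit are
#' excluded with their error message.
#'
#' @param data data.frame with the MV columns.
#' @param specs Named list of [plspm_spec()]s (>= 2).
#' @param k Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return data.frame sorted by rank, with an attribute `excluded` naming
#'   failed candidates.
#' @export
compare_architectures <- function(data, specs, k = 5, seed = 1) {
  if (length(specs) < 2L) stop("need at least 2 candidate architectures")
  if (is.null(names(specs))) names(specs) <- paste0("arch", seq_along(specs))
  rows <- list()
  excluded <- list()
  for (nm in names(specs)) {
    res <- tryCatch({
      ft <- fit_plspm(data, specs[[nm]])
      resp <- terminal_lvs(specs[[nm]])
      data.frame(architecture = nm,
                 response_r2 = mean(ft$r2[resp]),
                 gof = ft$gof,
                 cv_rmse = predict_response_rmse(data, specs[[nm]], k,
                                                 seed),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[nm]] <- conditionMessage(res)
    } else {
      rows[[nm]] <- res
    }
  }
  if (length(rows) == 0L) stop("every candidate architecture failed")
  out <- do.call(rbind, rows)
  out$rank <- rank(rank(-out$response_r2) + rank(-out$gof) +
                     rank(out$cv_rmse), ties.method = "min")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
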