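#' Build a PLS spec directly from a ground truth
#'
#' Blocks are the truth's measurement blocks plus one single-MV block per
#' generated response; arrows are the non-zero entries of the true path
#' matrix. Fitting this spec on data from [simulate_landscape()] is the
#' parameter-recovery setting: the estimated path coefficients can be
#' compared with the generating ones.
#'
#' @param truth A [ground_truth()].
#' @param scheme,tol,max_iter Passed to [plspm_spec()].
#' @return A [plspm_spec()].
#' @export
architecture_from_truth <- function(truth, scheme = "centroid",
                                    tol = 1e-7, max_iter = 300L) {
  B <- truth$path_matrix
  used <- rownames(B)[rowSums(B != 0) + colSums(B != 0) > 0]
  blocks <- lapply(intersect(names(truth$blocks), used), function(lvn) {
    plspm_block(lvn, truth$blocks[[lvn]])
  })
  for (lvn in intersect(names(truth$response_mvs), used)) {
    blocks[[length(blocks) + 1L]] <-
      plspm_block(lvn, names(truth$response_mvs[[lvn]]))
  }
  nz <- which(B != 0, arr.ind = TRUE)
  paths <- data.frame(from = rownames(B)[nz[, 1]],
                      to = colnames(B)[nz[, 2]],
                      stringsAsFactors = FALSE)
  plspm_spec(blocks, paths, scheme = scheme, tol = tol,
             max_iter = max_iter)
}

#' Default two-campaign path-model architecture
#'
#' The full architecture fitted in the demo workflow: exogenous land use
#' and habitat; campaign-specific copies of soil resources, crop rotation
#' and farming intensity; practice LVs feeding resources (mediation); land
#' use feeding rotation; every soil/practice LV feeding the response within
#' its campaign; and the temporal arrows rotation 2011 -> 2016 and
#' response 2011 -> 2016.
#'
#' @param response "smmb" or "richness" (names the response MV columns).
#' @param scheme,tol,max_iter Passed to [plspm_spec()].
#' @return A [plspm_spec()].
#' @export
default_architecture <- function(response = c("smmb", "richness"),
                                 scheme = "centroid", tol = 1e-7,
                                 max_iter = 300L) {
  response <- match.arg(response)
  gt <- default_ground_truth()
  blocks <- lapply(names(gt$blocks), function(lvn) {
    plspm_block(lvn, gt$blocks[[lvn]])
  })
  blocks[[length(blocks) + 1L]] <-
    plspm_block("response_2011", paste0(response, "_2011"))
  blocks[[length(blocks) + 1L]] <-
    plspm_block("response_2016", paste0(response, "_2016"))
  # land use enters only through rotation and resources: its response
  # effects are indirect, mirroring the mediation structure of the field
  # situation this architecture describes
  arrows <- rbind(
    expand.grid(from = c("habitat", "resources_2011",
                         "rotation_2011", "intensity_2011"),
                to = "response_2011", stringsAsFactors = FALSE),
    expand.grid(from = c("habitat", "resources_2016",
                         "rotation_2016", "intensity_2016"),
                to = "response_2016", stringsAsFactors = FALSE),
    data.frame(from = c("rotation_2011", "intensity_2011",
                        "rotation_2016", "intensity_2016",
                        "land_use", "land_use",
                        "rotation_2011", "response_2011"),
               to = c("resources_2011", "resources_2011",
                      "resources_2016", "resources_2016",
                      "rotation_2011", "rotation_2016",
                      "rotation_2016", "response_2016"),
               stringsAsFactors = FALSE))
  plspm_spec(blocks, arrows, scheme = scheme, tol = tol,
             max_iter = max_iter)
}

#' Campaign summary at landscape, forest and cropland scales
#'
#' Mean and standard error of a variable per campaign at the three scales,
#' with the paired Wilcoxon signed-rank comparison of the two campaigns
#' (stars: "." p < 0.1, "*" < 0.05, "**" < 0.01, "***" < 0.001, else NS).
#'
#' @param campaign_table Long table (one row per site x campaign) with
#'   `site_id`, `campaign`, `land_use` and the variable column.
#' @param variable Column name to summarize.
#' @return data.frame: one row per scale with per-campaign mean, SE, the
#'   test statistic, p-value and stars.
#' @export
summarize_by_scale <- function(campaign_table, variable) {
  if (!variable %in% names(campaign_table)) {
    stop(sprintf("variable '%s' not in table", variable))
  }
  cps <- sort(unique(campaign_table$campaign))
  if (length(cps) != 2L) stop("expected exactly two campaigns")
  scales <- list(landscape = rep(TRUE, nrow(campaign_table)),
                 forest = campaign_table$land_use == "forest",
                 cropland = campaign_table$land_use == "cropland")
  rows <- lapply(names(scales), function(sc) {
    sub <- campaign_table[scales[[sc]], , drop = FALSE]
    wide <- merge(
      sub[sub$campaign == cps[1], c("site_id", variable)],
      sub[sub$campaign == cps[2], c("site_id", variable)],
      by = "site_id", suffixes = c("_a", "_b"))
    va <- wide[[paste0(variable, "_a")]]
    vb <- wide[[paste0(variable, "_b")]]
    if (nrow(wide) < 3L) {
      warning(sprintf("scale '%s': fewer than 3 paired sites", sc))
      return(data.frame(variable = variable, scale = sc,
                        mean_1 = NA, se_1 = NA, mean_2 = NA, se_2 = NA,
                        statistic = NA, p_value = NA, stars = NA,
                        n = nrow(wide), stringsAsFactors = FALSE))
    }
    se <- function(v) stats::sd(v) / sqrt(length(v))
    wt <- paired_wilcoxon(va, vb)
    data.frame(variable = variable, scale = sc,
               mean_1 = mean(va), se_1 = se(va),
               mean_2 = mean(vb), se_2 = se(vb),
               statistic = wt$statistic, p_value = wt$p_value,
               stars = wt$stars, n = nrow(wide),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3:6] <- c(paste0(c("mean_", "se_"), cps[1]),
                       paste0(c("mean_", "se_"), cps[2]))
  out
}

#' Krige one variable of one campaign onto a prediction grid
#'
#' The full interpolated-mapping chain: normal-score transform, empirical
#' variogram, Matern fit by weighted NLS, leave-one-out validation (the run
#' aborts when the standardized errors fall outside the validity
#' envelopes), ordinary kriging in rank space over a regular grid, and
#' back-transformation.
#'
#' @param campaign_table Long campaign table.
#' @param variable Column to map.
#' @param campaign Campaign year.
#' @param grid_n Prediction grid is `grid_n x grid_n`.
#' @param mean_envelope,med_envelope LOO validity envelopes (see
#'   [loo_crossvalidate()]).
#' @param kappa_grid Smoothness grid for [fit_matern()].
#' @return List: `surface` (grid data.frame with rank-space estimate,
#'   variance and back-transformed `value`), `fit`, `cv`, `rankmap`.
#' @export
krige_variable <- function(campaign_table, variable, campaign, grid_n = 25,
                           mean_envelope = 0.1, med_envelope = 0.12,
                           kappa_grid = c(0.5, 1, 1.5, 2.5)) {
  sub <- campaign_table[campaign_table$campaign == campaign, , drop = FALSE]
  coords <- cbind(sub$x, sub$y)
  rm <- rank_transform(sub[[variable]])
  ev <- empirical_variogram(coords, rm$scores)
  ft <- fit_matern(ev, kappa_grid = kappa_grid)
  cv <- loo_crossvalidate(coords, rm$scores, ft$model,
                          mean_envelope = mean_envelope,
                          med_envelope = med_envelope)
  if (!cv$valid) {
    stop(sprintf(
      "kriging model for %s (%s) failed LOO validation: Theta-mean %.3f, Theta-med %.3f",
      variable, campaign, cv$theta_mean, cv$theta_med))
  }
  gx <- seq(min(sub$x), max(sub$x), length.out = grid_n)
  gy <- seq(min(sub$y), max(sub$y), length.out = grid_n)
  targets <- as.matrix(expand.grid(x = gx, y = gy))
  surf <- ordinary_krige(coords, rm$scores, ft$model, targets)
  surf$value <- as.numeric(back_transform(surf$estimate, rm))
  list(surface = surf, fit = ft, cv = cv, rankmap = rm)
}

write_csv_out <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis chain on a synthetic landscape
#'
#' Simulate (or accept) a landscape, compute the campaign summary table,
#' kriged maps with LOO validation for the configured variables, paired
#' campaign comparisons, and the two path models (biomass-like and
#' richness-like responses) with effects, GOF and bootstrap validation.
#' All tables and reports are written under `config$outdir` together with
#' a manifest of md5 checksums; rerunning with the same config reproduces
#' the manifest bit-identically.
#'
#' @param config A list: `seed`, `outdir`, `noise_sd`, `krige_vars`
#'   (character), `grid_n`, `n_boot`, `mean_envelope`, `med_envelope`.
#'   Missing entries take the defaults of [run_config()].
#' @param landscape Optionally, a pre-built [simulate_landscape()] result.
#' @return Invisibly, a list with every artifact and the manifest path.
#' @export
run_all <- function(config = run_config(), landscape = NULL) {
  config <- utils::modifyList(run_config(), config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  land <- if (is.null(landscape)) {
    simulate_landscape(seed = config$seed, noise_sd = config$noise_sd)
  } else landscape

  files <- c(
    sites = write_csv_out(land$sites, file.path(config$outdir,
                                                "sites.csv")),
    soil = write_csv_out(land$soil, file.path(config$outdir, "soil.csv")),
    climate = write_csv_out(land$climate,
                            file.path(config$outdir, "climate.csv")),
    operations = write_csv_out(land$operations,
                               file.path(config$outdir, "operations.csv")),
    applications = write_csv_out(
      land$applications, file.path(config$outdir, "applications.csv")),
    indicators = write_csv_out(
      land$indicators, file.path(config$outdir, "indicators.csv")),
    campaign = write_csv_out(
      land$campaign_table, file.path(config$outdir, "campaign_table.csv")))

  truth_out <- list(
    smmb_path_matrix = land$truth$path_matrix,
    richness_path_matrix = land$richness_truth$path_matrix,
    noise_sd = land$truth$noise_sd, seed = land$seed)
  jsonlite::write_json(truth_out,
                       file.path(config$outdir, "truth.json"),
                       matrix = "rowmajor", digits = NA)
  files["truth"] <- file.path(config$outdir, "truth.json")

  summary_vars <- intersect(
    c("smmb", "richness", "water_stress", "SOC", "TN", "CN", "pH",
      "Freq_winter", "Freq_plowing", "TFI_total", "N", "P", "K"),
    names(land$campaign_table))
  table1 <- do.call(rbind, lapply(summary_vars, function(v) {
    summarize_by_scale(land$campaign_table, v)
  }))
  files["summary"] <- write_csv_out(table1, file.path(config$outdir,
                                                      "summary_table.csv"))

  krige_reports <- list()
  for (v in config$krige_vars) {
    for (cy in sort(unique(land$campaign_table$campaign))) {
      kr <- krige_variable(land$campaign_table, v, cy,
                           grid_n = config$grid_n,
                           mean_envelope = config$mean_envelope,
                           med_envelope = config$med_envelope)
      key <- sprintf("%s_%s", v, cy)
      files[paste0("surface_", key)] <- write_csv_out(
        kr$surface, file.path(config$outdir,
                              sprintf("surface_%s.csv", key)))
      krige_reports[[key]] <- list(
        variable = v, campaign = cy,
        model = unclass(kr$fit$model), objective = kr$fit$objective,
        theta_mean = kr$cv$theta_mean, theta_med = kr$cv$theta_med,
        valid = kr$cv$valid)
    }
  }
  jsonlite::write_json(krige_reports,
                       file.path(config$outdir, "kriging_reports.json"),
                       auto_unbox = TRUE, digits = NA)
  files["kriging_reports"] <- file.path(config$outdir,
                                        "kriging_reports.json")

  models <- list()
  for (resp in c("smmb", "richness")) {
    tr <- if (resp == "smmb") land$truth else land$richness_truth
    spec <- architecture_from_truth(tr)
    fit <- fit_plspm(land$model_table, spec)
    eff <- effects_decomposition(fit$path)
    gf <- gof(fit)
    boot <- bootstrap_validate(land$model_table, spec,
                               n_boot = config$n_boot,
                               seed = config$seed + 7000L)
    models[[resp]] <- list(fit = fit, effects = eff, gof = gf,
                           bootstrap = boot)
    report <- list(r2 = as.list(fit$r2[fit$spec$endogenous]),
                   gof = gf$gof, gof_label = gf$label,
                   paths = fit$path_table,
                   effects = eff$table,
                   bootstrap = boot$table)
    jsonlite::write_json(report,
                         file.path(config$outdir,
                                   sprintf("plspm_%s.json", resp)),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files[paste0("plspm_", resp)] <- file.path(
      config$outdir, sprintf("plspm_%s.json", resp))
  }

  manifest <- data.frame(file = basename(unname(files)),
                         md5 = unname(tools::md5sum(unname(files))),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(list(landscape = land, summary = table1,
                 kriging = krige_reports, models = models,
                 files = files,
                 manifest = file.path(config$outdir, "manifest.json")))
}

#' Default run configuration
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @param noise_sd Response measurement noise.
#' @param krige_vars Variables to map (per campaign).
#' @param grid_n Prediction grid side.
#' @param n_boot Bootstrap resamples for the demo models (the reference
#'   analysis uses 10,000; the demo default keeps runs short).
#' @param mean_envelope,med_envelope LOO validity envelopes.
#' @return A config list for [run_all()].
#' @export
run_config <- function(seed = 1, outdir = "results/run",
                       noise_sd = 0.3,
                       krige_vars = c("SOC", "smmb"),
                       grid_n = 25, n_boot = 30,
                       mean_envelope = 0.1, med_envelope = 0.12) {
  list(seed = seed, outdir = outdir, noise_sd = noise_sd,
       krige_vars = krige_vars, grid_n = grid_n, n_boot = n_boot,
       mean_envelope = mean_envelope, med_envelope = med_envelope)
}
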