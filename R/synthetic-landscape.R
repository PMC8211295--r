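#' Generate a synthetic sampling design: regular grid plus random sites
#'
#' Emulates a landscape survey: a regular square grid (default 215 m
#' spacing) plus `n_random` uniformly placed extra sites, with a minimum
#' inter-site distance enforced by rejection sampling. Sites are assigned to
#' polygonal plots by nearest plot seed (a Voronoi tessellation), and one
#' contiguous region of plots is labelled forest so that roughly
#' `forest_fraction` of the sites fall in forest.
#'
#' @param grid_spacing Grid step (m).
#' @param extent c(width, height) of the rectangular landscape (m).
#' @param n_random Number of extra random sites.
#' @param n_retain If fewer than the generated total, sites are dropped at
#'   random down to this count (emulating field exclusions). NULL keeps all.
#' @param forest_fraction Target fraction of sites in forest (0 <= f < 1).
#' @param min_dist Minimum distance between any two sites (m).
#' @param n_plots Number of plot seeds for the Voronoi tessellation.
#' @param seed Integer seed; the whole table is reproducible from it.
#' @return data.frame: `site_id`, `x`, `y`, `plot_id`, `land_use`
#'   ("forest"/"cropland").
#' @export
make_sites <- function(grid_spacing = 215, extent = c(3225, 3440),
                       n_random = 30, n_retain = 269,
                       forest_fraction = 43 / 269, min_dist = 30,
                       n_plots = 80, seed = 1) {
  stopifnot(grid_spacing > 0, length(extent) == 2, all(extent > 0),
            n_random >= 0, forest_fraction >= 0, forest_fraction < 1)
  if (min_dist > grid_spacing) {
    stop("minimum distance exceeds the grid spacing")
  }
  set.seed(seed)
  half <- grid_spacing / 2
  if (extent[1] < grid_spacing || extent[2] < grid_spacing) {
    stop("extent too small for the grid spacing")
  }
  gx <- seq(half, extent[1] - half, by = grid_spacing)
  gy <- seq(half, extent[2] - half, by = grid_spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  # random extra sites, rejection-sampled for the minimum distance
  fails <- 0L
  placed <- 0L
  while (placed < n_random) {
    cand <- c(stats::runif(1, 0, extent[1]), stats::runif(1, 0, extent[2]))
    d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2
    if (min(d2) >= min_dist^2) {
      pts <- rbind(pts, cand)
      placed <- placed + 1L
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > 5000L) {
        stop("extent too small to honor the minimum inter-site distance")
      }
    }
  }
  n <- nrow(pts)
  if (!is.null(n_retain)) {
    if (n_retain > n) stop("n_retain exceeds the number of generated sites")
    keep <- sort(sample.int(n, n_retain))
    pts <- pts[keep, , drop = FALSE]
    n <- n_retain
  }
  # Voronoi plot membership from uniform plot seeds
  px <- stats::runif(n_plots, 0, extent[1])
  py <- stats::runif(n_plots, 0, extent[2])
  plot_of <- apply(pts, 1, function(p) {
    which.min((px - p[1])^2 + (py - p[2])^2)
  })
  land_use <- rep("cropland", n)
  if (forest_fraction > 0) {
    # grow a contiguous forest region: plots ordered by distance of their
    # seed from a randomly chosen corner of the landscape
    corner <- rbind(c(0, 0), c(extent[1], 0), c(0, extent[2]), extent)[
      sample.int(4, 1), ]
    ord <- order((px - corner[1])^2 + (py - corner[2])^2)
    target <- round(forest_fraction * n)
    got <- 0L
    forest_plots <- integer(0)
    for (pl in ord) {
      if (got >= target) break
      forest_plots <- c(forest_plots, pl)
      got <- got + sum(plot_of == pl)
    }
    land_use[plot_of %in% forest_plots] <- "forest"
  }
  data.frame(site_id = sprintf("S%03d", seq_len(n)),
             x = unname(pts[, 1]), y = unname(pts[, 2]),
             plot_id = sprintf("P%02d", plot_of),
             land_use = land_use,
             stringsAsFactors = FALSE)
}

#' Simulate spatially autocorrelated soil fields at the sites
#'
#' Draws jointly Gaussian fields with Matern correlation at the site
#' coordinates, one per named spec, with an additive land-use offset for
#' forest sites. The variogram gives the correlation shape (partial sill
#' and nugget are normalized to unit total variance); `mean`/`sd` set the
#' observation scale.
#'
#' @param sites Output of [make_sites()].
#' @param field_specs Named list; each element a list with `model` (a
#'   [matern_variogram()]), `mean`, `sd`, optional `forest_offset` and
#'   optional `forest_sd_extra` (independent extra spread on forest sites;
#'   forest soils are typically far more heterogeneous than cropland).
#' @param seed Integer seed.
#' @return data.frame with `site_id` and one column per field.
#' @export
simulate_soil_fields <- function(sites, field_specs, seed = 1) {
  set.seed(seed)
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  n <- nrow(d)
  is_forest <- sites$land_use == "forest"
  out <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  for (nm in names(field_specs)) {
    fs <- field_specs[[nm]]
    m <- fs$model
    if (m$psill <= 0 && m$nugget <= 0) stop("spec needs a positive sill")
    Rho <- matern_cov(d, m) / (m$psill + m$nugget)
    L <- tryCatch(chol(Rho), error = function(e) NULL)
    if (is.null(L)) {
      warning(sprintf("field '%s': covariance not PD, jittering diagonal",
                      nm))
      L <- chol(Rho + diag(1e-6, n))
    }
    z <- drop(crossprod(L, stats::rnorm(n)))
    off <- if (is.null(fs$forest_offset)) 0 else fs$forest_offset
    fx <- if (is.null(fs$forest_sd_extra)) 0 else fs$forest_sd_extra
    sdv <- if (is.null(fs$sd)) 1 else fs$sd
    mnv <- if (is.null(fs$mean)) 0 else fs$mean
    out[[nm]] <- mnv + sdv * z + off * is_forest +
      fx * stats::rnorm(n) * is_forest
  }
  out
}

#' Close a texture composition to 100 percent
#'
#' Clamps components below a small floor and rescales so that
#' clay + silt + sand = 100.
#'
#' @param clay,silt,sand Percentages (vectors).
#' @return data.frame with closed `clay`, `silt`, `sand`.
#' @export
close_texture <- function(clay, silt, sand) {
  m <- cbind(pmax(clay, 1), pmax(silt, 1), pmax(sand, 1))
  m <- 100 * m / rowSums(m)
  data.frame(clay = m[, 1], silt = m[, 2], sand = m[, 3])
}

#' Simulate a daily climate series
#'
#' Rainfall: first-order wet/dry occurrence with gamma amounts; potential
#' evapotranspiration: smooth seasonal cycle peaking in midsummer plus
#' weather noise. A per-farming-year rainfall multiplier lets campaigns
#' differ in wetness (defaults make the 2016 farming year wetter than 2011,
#' so downstream water-stress counts drop between campaigns).
#'
#' @param start_year,end_year Farming-year labels covered (series runs from
#'   1 Sept of `start_year - 1` to 31 Aug of `end_year`).
#' @param rain_factor Named numeric: multiplier on rainfall amounts per
#'   farming year (unnamed years get 1).
#' @param seed Integer seed.
#' @return data.frame: `date`, `RR` (mm), `ETPp` (mm/day).
#' @export
simulate_climate <- function(start_year = 2010, end_year = 2016,
                             rain_factor = c("2011" = 0.7, "2016" = 1.4),
                             seed = 1) {
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-09-01", start_year - 1L)),
               as.Date(sprintf("%d-08-31", end_year)), by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  fy <- ifelse(mo >= 9, yr + 1L, yr)
  etp <- pmax(0, 2.4 - 2.1 * cos(2 * pi * (doy - 15) / 365.25) +
                stats::rnorm(nd, 0, 0.35))
  p_wet <- 0.38 - 0.06 * cos(2 * pi * (doy - 350) / 365.25)
  wet <- stats::runif(nd) < p_wet
  amount <- stats::rgamma(nd, shape = 0.9, scale = 6.2)
  fac <- rain_factor[as.character(fy)]
  fac[is.na(fac)] <- 1
  data.frame(date = dates,
             RR = ifelse(wet, amount * fac, 0),
             ETPp = etp)
}

#' Default crop rotation menu
#'
#' Base sampling weights per species plus the plot-trait response used by
#' [simulate_farm_history()]: plots with a high rotation trait favor winter
#' cereals (and spread across several winter species), plots with a low
#' trait lean on spring/summer crops. Weights are calibrated loosely to the
#' winter-crop-heavy crop-type proportions typical of intensive cereal
#' landscapes.
#'
#' @return data.frame: `species`, `weight`, `winter_cereal`, `minor_winter`,
#'   `spring_summer`.
#' @export
default_rotation_menu <- function() {
  cls <- default_crop_classes()
  sp <- cls$species
  w <- c(winter_wheat = 0.33, winter_barley = 0.11, triticale = 0.05,
         rye = 0.02, rapeseed = 0.20, mustard = 0.02, maize = 0.07,
         sunflower = 0.03, pea = 0.07, spring_barley = 0.05,
         fallow = 0.03, blackcurrant = 0.01, miscanthus = 0.01)
  data.frame(
    species = sp,
    weight = unname(w[sp]),
    winter_cereal = cls$crop_type == "winter",
    minor_winter = sp %in% c("winter_barley", "triticale", "rye"),
    spring_summer = cls$crop_type %in% c("spring", "summer"),
    stringsAsFactors = FALSE
  )
}

#' Default farming-intensity profile
#'
#' Two practice regimes bracketing the study period: the early regime is
#' plowing-dominated with lower pesticide pressure; the late regime has much
#' less plowing, more frequent non-inversion tillage and no-till, higher
#' pesticide TFIs, and shifted fertilizer totals. With drift enabled the
#' regimes are linearly interpolated between the two campaign years.
#'
#' @return A list with elements `early`, `late` (each: `tillage_probs`,
#'   `app_rate`, `fert_mean`), `fert_cv`, `dose_range`, `drift_years`.
#' @export
default_intensity_profile <- function() {
  list(
    early = list(
      tillage_probs = c(none = 0.01, intermediate = 0.03,
                        decompacting = 0.01, plowing = 0.95),
      app_rate = c(herbicide = 2.6, fungicide = 1.7, insecticide = 0.5,
                   anti_slug = 0.35),
      fert_mean = c(N = 137, P = 52, K = 36, Mg = 7, S = 33)
    ),
    late = list(
      tillage_probs = c(none = 0.18, intermediate = 0.32,
                        decompacting = 0.26, plowing = 0.24),
      app_rate = c(herbicide = 3.3, fungicide = 2.7, insecticide = 0.65,
                   anti_slug = 0.45),
      fert_mean = c(N = 158, P = 43, K = 25, Mg = 14, S = 52)
    ),
    fert_cv = 0.25,
    dose_range = c(0.5, 1.05),
    drift_years = c(2011, 2016)
  )
}

#' Simulate plot-level farm operation logs
#'
#' Per cropland plot and farming year: a crop drawn from a Markovian
#' rotation (persistent plot-level traits set winter-crop affinity and
#' rotation diversity; repeating last year's crop, and especially rapeseed
#' after rapeseed, is penalized), a tillage category, pesticide applications
#' with applied and recommended doses, and fertilizer totals. With
#' `drift = TRUE` practices move from the early to the late regime of the
#' intensity profile between the two campaign years; with `drift = FALSE`
#' the early regime applies throughout.
#'
#' @param plots data.frame with `plot_id`, `land_use` (forest plots are
#'   skipped).
#' @param years Farming years to simulate.
#' @param menu Rotation menu ([default_rotation_menu()]).
#' @param profile Intensity profile ([default_intensity_profile()]).
#' @param drift Enable the temporal practice drift.
#' @param seed Integer seed.
#' @return A list: `operations` (plot-year rows: `plot_id`, `farming_year`,
#'   `species`, `crop_type`, `tillage`, `N`, `P`, `K`, `Mg`, `S`),
#'   `applications` (event rows: `plot_id`, `date`, `category`,
#'   `applied_dose`, `recommended_dose`), `traits` (per-plot latent traits).
#' @export
simulate_farm_history <- function(plots, years = 2004:2016,
                                  menu = default_rotation_menu(),
                                  profile = default_intensity_profile(),
                                  drift = TRUE, seed = 1) {
  if (nrow(menu) == 0L) stop("rotation menu must be non-empty")
  set.seed(seed)
  cls <- default_crop_classes()
  crop <- plots[plots$land_use != "forest", , drop = FALSE]
  crop <- crop[!duplicated(crop$plot_id), , drop = FALSE]
  np <- nrow(crop)
  u <- stats::rnorm(np)   # rotation trait: winter affinity + diversity
  v <- stats::rnorm(np)   # intensity trait
  y0 <- profile$drift_years[1]
  y1 <- profile$drift_years[2]
  mix <- function(year, a, b) {
    t <- if (drift) min(max((year - y0) / (y1 - y0), 0), 1) else 0
    (1 - t) * a + t * b
  }
  ops <- vector("list", np)
  apps <- vector("list", np)
  for (i in seq_len(np)) {
    pid <- crop$plot_id[i]
    last <- NA_character_
    rows <- vector("list", length(years))
    evts <- list()
    for (k in seq_along(years)) {
      y <- years[k]
      w <- menu$weight *
        exp(0.9 * u[i] * menu$winter_cereal) *
        exp(0.6 * u[i] * menu$minor_winter) *
        exp(-0.7 * u[i] * menu$spring_summer)
      if (!is.na(last)) {
        w[menu$species == last] <- w[menu$species == last] *
          if (last == "rapeseed") 0.05 else 0.35
      }
      sp <- sample(menu$species, 1, prob = w)
      last <- sp
      tp <- mix(y, profile$early$tillage_probs, profile$late$tillage_probs)
      tp["plowing"] <- tp["plowing"] * exp(0.6 * v[i])
      tp["none"] <- tp["none"] * exp(-0.6 * v[i])
      tillage <- sample(names(tp), 1, prob = tp)
      fm <- mix(y, profile$early$fert_mean, profile$late$fert_mean) *
        exp(0.3 * v[i])
      fert <- pmax(0, stats::rnorm(5, fm, profile$fert_cv * fm))
      rate <- mix(y, profile$early$app_rate, profile$late$app_rate) *
        exp(0.4 * v[i])
      n_apps <- stats::rpois(length(rate), rate)
      for (ci in seq_along(n_apps)) {
        if (n_apps[ci] == 0) next
        offs <- sort(sample.int(300, n_apps[ci], replace = TRUE))
        evts[[length(evts) + 1L]] <- data.frame(
          plot_id = pid,
          date = as.Date(sprintf("%d-09-01", y - 1L)) + 30 + offs,
          category = names(rate)[ci],
          applied_dose = stats::runif(n_apps[ci], profile$dose_range[1],
                                      profile$dose_range[2]),
          recommended_dose = 1,
          stringsAsFactors = FALSE)
      }
      rows[[k]] <- data.frame(
        plot_id = pid, farming_year = y, species = sp,
        crop_type = cls$crop_type[match(sp, cls$species)],
        tillage = tillage,
        N = fert[1], P = fert[2], K = fert[3], Mg = fert[4], S = fert[5],
        stringsAsFactors = FALSE)
    }
    ops[[i]] <- do.call(rbind, rows)
    apps[[i]] <- if (length(evts)) do.call(rbind, evts) else NULL
  }
  list(operations = do.call(rbind, ops),
       applications = do.call(rbind, Filter(Negate(is.null), apps)),
       traits = data.frame(plot_id = crop$plot_id, rotation_trait = u,
                           intensity_trait = v, stringsAsFactors = FALSE))
}

topological_order <- function(B) {
  lv <- rownames(B)
  order <- character(0)
  remaining <- lv
  while (length(remaining) > 0) {
    free <- remaining[colSums(abs(B[remaining, remaining, drop = FALSE]))
                      == 0]
    if (length(free) == 0) {
      stop("path-coefficient matrix is cyclic (not nilpotent)")
    }
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
  }
  order
}

#' Ground truth for the synthetic data-generating process
#'
#' Records the true standardized path coefficients, the measurement blocks
#' used to build exogenous latent-variable scores, the observation scales of
#' the generated responses, and the noise level, so that every downstream
#' stage can be scored against a known answer.
#'
#' @param path_matrix Square named matrix, `path_matrix[from, to]` = true
#'   standardized coefficient; must be acyclic.
#' @param blocks Named list: LV -> character vector of MV column names
#'   (exogenous LVs are scored as the standardized equal-weight mean of
#'   their standardized MVs, sign-anchored to the first MV).
#' @param response_mvs Named list for generated (endogenous-with-emission)
#'   LVs: LV -> named list of MV -> c(center, scale).
#' @param noise_sd Measurement noise (sd, standardized MV scale) added when
#'   emitting generated MVs.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(path_matrix, blocks, response_mvs,
                         noise_sd = 0.3) {
  stopifnot(is.matrix(path_matrix),
            nrow(path_matrix) == ncol(path_matrix),
            !is.null(rownames(path_matrix)),
            identical(rownames(path_matrix), colnames(path_matrix)))
  topological_order(path_matrix)  # errors if cyclic
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(path_matrix = path_matrix, blocks = blocks,
                 response_mvs = response_mvs, noise_sd = noise_sd),
            class = "ground_truth")
}

#' Default ground truth for the landscape generator
#'
#' Ten latent variables: exogenous land use (forest-ness), habitat and the
#' campaign-specific soil-resource, crop-rotation and farming-intensity
#' blocks scored from the simulated data; generated microbial responses
#' (one per campaign) driven by standardized path coefficients whose signs
#' echo the field situation the generator emulates (resources and habitat
#' positive, farming intensity negative, a temporal carry-over between
#' campaigns), with an affine map onto a biomass-like observation scale.
#'
#' @param noise_sd Measurement noise for the emitted responses.
#' @return A `ground_truth` object.
#' @export
default_ground_truth <- function(noise_sd = 0.3) {
  lv <- c("land_use", "habitat",
          "resources_2011", "resources_2016",
          "rotation_2011", "rotation_2016",
          "intensity_2011", "intensity_2016",
          "response_2011", "response_2016")
  B <- matrix(0, 10, 10, dimnames = list(lv, lv))
  B["resources_2011", "response_2011"] <- 0.45
  B["resources_2016", "response_2016"] <- 0.45
  B["habitat", "response_2011"] <- 0.15
  B["habitat", "response_2016"] <- 0.15
  B["intensity_2011", "response_2011"] <- -0.2
  B["intensity_2016", "response_2016"] <- -0.2
  B["rotation_2011", "response_2011"] <- -0.15
  B["rotation_2016", "response_2016"] <- 0.15
  B["response_2011", "response_2016"] <- 0.25
  blocks <- list(
    land_use = "forest",
    habitat = c("clay", "silt"),
    resources_2011 = c("SOC_2011", "TN_2011", "water_stress_2011"),
    resources_2016 = c("SOC_2016", "TN_2016", "water_stress_2016"),
    rotation_2011 = c("winter_crop_2011", "nbr_species_2011",
                      "Freq_winter_2011"),
    rotation_2016 = c("winter_crop_2016", "nbr_species_2016",
                      "Freq_winter_2016"),
    intensity_2011 = c("Freq_plowing_2011", "TFI_fungicide_2011",
                       "TFI_total_2011", "P_2011", "K_2011", "S_2011"),
    intensity_2016 = c("Freq_plowing_2016", "TFI_fungicide_2016",
                       "TFI_total_2016", "P_2016", "K_2016", "S_2016")
  )
  # identical observation scales for the two campaigns, so that with the
  # practice drift disabled and zero noise the campaigns coincide exactly
  response_mvs <- list(
    response_2011 = list(smmb_2011 = c(65, 35)),
    response_2016 = list(smmb_2016 = c(65, 35))
  )
  ground_truth(B, blocks, response_mvs, noise_sd = noise_sd)
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance variable")
  (x - mean(x)) / s
}

exogenous_score <- function(data, mvs) {
  X <- sapply(mvs, function(m) standardize(data[[m]]))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  sc <- standardize(rowMeans(X))
  if (stats::cor(sc, X[, 1]) < 0) sc <- -sc
  sc
}

#' Generate microbial responses from the true path structure
#'
#' Builds standardized latent-variable scores from the generated measured
#' variables (exogenous blocks), then propagates them through the true path
#' matrix in topological order. Each generated LV equals its structural
#' fitted value plus a residual drawn once per base LV (campaign suffix
#' stripped), made exactly orthogonal in sample to the predecessors and
#' scaled so the score has unit sample variance - so a regression of the
#' realized scores recovers the true coefficients exactly. Generated MVs
#' are emitted as `center + scale * (score + noise_sd * eps)`.
#'
#' @param data data.frame, one row per site, holding every MV column named
#'   in the truth's blocks.
#' @param truth A [ground_truth()].
#' @param seed Integer seed.
#' @return A list: `responses` (data.frame of emitted MVs), `scores`
#'   (realized LV scores), `truth`.
#' @export
simulate_responses <- function(data, truth, seed = 1) {
  if (!inherits(truth, "ground_truth")) stop("`truth` must be ground_truth")
  set.seed(seed)
  B <- truth$path_matrix
  ord <- topological_order(B)
  n <- nrow(data)
  scores <- matrix(NA_real_, n, length(ord),
                   dimnames = list(NULL, rownames(B)))
  base_resid <- new.env(parent = emptyenv())
  for (lvn in ord) {
    preds <- rownames(B)[B[, lvn] != 0]
    if (length(preds) == 0 && !lvn %in% names(truth$response_mvs)) {
      if (is.null(truth$blocks[[lvn]])) {
        stop(sprintf("exogenous LV '%s' has no measurement block", lvn))
      }
      scores[, lvn] <- exogenous_score(data, truth$blocks[[lvn]])
    } else if (length(preds) == 0) {
      # generated LV with no structural parents: pure standardized noise
      base <- sub("_[0-9]{4}$", "", lvn)
      if (is.null(base_resid[[base]])) {
        base_resid[[base]] <- stats::rnorm(n)
      }
      scores[, lvn] <- standardize(base_resid[[base]])
    } else {
      fitted <- scores[, preds, drop = FALSE] %*% B[preds, lvn]
      base <- sub("_[0-9]{4}$", "", lvn)
      if (is.null(base_resid[[base]])) {
        base_resid[[base]] <- stats::rnorm(n)
      }
      raw <- base_resid[[base]]
      eta <- stats::lm.fit(cbind(1, scores[, preds, drop = FALSE]),
                           raw)$residuals
      if (stats::var(eta) < 1e-6 * stats::var(raw)) {
        # the shared campaign residual is collinear with a predecessor
        # (e.g. a direct temporal self-arrow): use a fresh draw instead
        if (is.null(base_resid[[lvn]])) base_resid[[lvn]] <- stats::rnorm(n)
        raw <- base_resid[[lvn]]
        eta <- stats::lm.fit(cbind(1, scores[, preds, drop = FALSE]),
                             raw)$residuals
      }
      vf <- stats::var(as.vector(fitted))
      if (vf >= 1) {
        warning(sprintf(
          "LV '%s': structural fitted variance %.3f >= 1; no residual added",
          lvn, vf))
        scores[, lvn] <- fitted
      } else {
        scores[, lvn] <- fitted + eta * sqrt((1 - vf) / stats::var(eta))
      }
    }
  }
  responses <- data.frame(row.names = seq_len(n))
  for (lvn in names(truth$response_mvs)) {
    for (mvn in names(truth$response_mvs[[lvn]])) {
      cs <- truth$response_mvs[[lvn]][[mvn]]
      obs <- scores[, lvn] + truth$noise_sd * stats::rnorm(n)
      responses[[mvn]] <- cs[1] + cs[2] * obs
    }
  }
  list(responses = responses, scores = as.data.frame(scores), truth = truth)
}
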