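#' Default soil-field specifications
#'
#' Matern-correlated fields on observation scales loosely calibrated to a
#' clayey/silty-loam arable landscape with forest patches: forest soils
#' carry much higher organic carbon (about 2.3x the cropland mean) and
#' slightly lower pH; texture is time-invariant; small `*_delta` fields
#' perturb the stable soil properties between the two campaigns.
#'
#' @return Named list of field specs for [simulate_soil_fields()].
#' @export
default_soil_specs <- function() {
  list(
    SOC_2011 = list(model = matern_variogram(0.1, 0.9, 200, 0.5),
                    mean = 17.6, sd = 6.5, forest_offset = 23.5,
                    forest_sd_extra = 12),
    pH_2011 = list(model = matern_variogram(0.15, 0.85, 150, 0.5),
                   mean = 7.8, sd = 0.5, forest_offset = -0.7,
                   forest_sd_extra = 0.8),
    clay = list(model = matern_variogram(0.1, 0.9, 250, 0.5),
                mean = 33.4, sd = 6, forest_offset = -0.8,
                forest_sd_extra = 10),
    silt_dev = list(model = matern_variogram(0.2, 0.8, 200, 0.5),
                    mean = 0, sd = 3.5, forest_offset = 0.7),
    soil_depth = list(model = matern_variogram(0.2, 0.8, 300, 0.5),
                      mean = 80, sd = 15, forest_offset = -10),
    soc_delta = list(model = matern_variogram(0.3, 0.7, 150, 0.5),
                     mean = 0, sd = 1.0),
    ph_delta = list(model = matern_variogram(0.3, 0.7, 150, 0.5),
                    mean = -0.06, sd = 0.08)
  )
}

#' Ground truth variant for a richness-like response
#'
#' Same latent structure as [default_ground_truth()] but with path signs
#' echoing a bacterial-richness situation: habitat and land use (forest)
#' negative, practice effects positive and weaker, and a strong temporal
#' carry-over; emitted on an OTU-count-like scale.
#'
#' @param noise_sd Measurement noise for the emitted responses.
#' @return A `ground_truth` object.
#' @export
default_richness_truth <- function(noise_sd = 0.3) {
  gt <- default_ground_truth(noise_sd)
  B <- gt$path_matrix
  B[] <- 0
  B["resources_2011", "response_2011"] <- 0.3
  B["resources_2016", "response_2016"] <- 0.3
  B["habitat", "response_2011"] <- -0.2
  B["habitat", "response_2016"] <- -0.2
  B["intensity_2011", "response_2011"] <- 0.1
  B["intensity_2016", "response_2016"] <- 0.1
  B["rotation_2011", "response_2011"] <- 0.25
  B["rotation_2016", "response_2016"] <- 0.15
  B["response_2011", "response_2016"] <- 0.4
  ground_truth(B, gt$blocks,
               list(response_2011 = list(richness_2011 = c(1925, 60)),
                    response_2016 = list(richness_2016 = c(1925, 60))),
               noise_sd = noise_sd)
}

#' Simulate a complete synthetic landscape study
#'
#' End-to-end generator: sampling design, autocorrelated soil fields,
#' daily climate, 2004-2016 farm operation logs, per-site water-stress
#' counts for the two campaign farming years, the 17 practice indicators,
#' and microbial responses (biomass-like and richness-like) generated from
#' known path-coefficient structures. Everything is reproducible from
#' `seed`.
#'
#' @param seed Integer master seed (stage seeds are derived from it).
#' @param noise_sd Measurement noise of the emitted responses.
#' @param drift Enable the temporal practice drift between campaigns.
#' @param campaigns The two campaign (sampling) years.
#' @param truth Ground truth for the biomass-like response.
#' @param richness_truth Ground truth for the richness-like response.
#' @param ... Passed to [make_sites()] (extent, spacing, fractions, ...).
#' @return A list of class `synthetic_landscape`: `sites`, `soil` (wide,
#'   per site), `climate`, `operations`, `applications`, `indicators`
#'   (per plot x campaign), `model_table` (one row per site, every MV
#'   column), `campaign_table` (long, one row per site x campaign),
#'   `scores`, `truth`, `richness_truth`, `seed`.
#' @export
simulate_landscape <- function(seed = 1, noise_sd = 0.3, drift = TRUE,
                               campaigns = c(2011, 2016),
                               truth = default_ground_truth(noise_sd),
                               richness_truth =
                                 default_richness_truth(noise_sd),
                               ...) {
  sites <- make_sites(seed = seed, ...)
  n <- nrow(sites)
  fields <- simulate_soil_fields(sites, default_soil_specs(),
                                 seed = seed + 1000L)
  set.seed(seed + 4000L)
  soil <- data.frame(site_id = sites$site_id, stringsAsFactors = FALSE)
  tex <- close_texture(fields$clay,
                       56 + 0.55 * (fields$clay - 33.4) + fields$silt_dev,
                       100 - fields$clay -
                         (56 + 0.55 * (fields$clay - 33.4) +
                            fields$silt_dev))
  soil$clay <- tex$clay
  soil$silt <- tex$silt
  soil$sand <- tex$sand
  soil$soil_depth <- pmin(pmax(fields$soil_depth, 25), 120)
  soil$SOC_2011 <- pmax(fields$SOC_2011, 2)
  soil$SOC_2016 <- pmax(soil$SOC_2011 + fields$soc_delta, 2)
  soil$TN_2011 <- pmax(soil$SOC_2011 / 10.68 + stats::rnorm(n, 0, 0.15),
                       0.2)
  soil$TN_2016 <- pmax(soil$SOC_2016 / 10.07 + stats::rnorm(n, 0, 0.15),
                       0.2)
  soil$pH_2011 <- fields$pH_2011
  soil$pH_2016 <- fields$pH_2011 + fields$ph_delta

  climate <- simulate_climate(min(campaigns) - 1L, max(campaigns),
                              seed = seed + 2000L)
  plots <- sites[!duplicated(sites$plot_id),
                 c("plot_id", "land_use"), drop = FALSE]
  farm <- simulate_farm_history(plots, years = (min(campaigns) - 7L):
                                  max(campaigns),
                                drift = drift, seed = seed + 3000L)

  # per-site cumulative water-stress days for each campaign farming year
  crop_of <- function(plot, year) {
    if (sites$land_use[match(plot, sites$plot_id)] == "forest") {
      return("forest")
    }
    sp <- farm$operations$species[farm$operations$plot_id == plot &
                                    farm$operations$farming_year == year]
    if (length(sp) != 1L) stop(sprintf("plot %s: no crop for %d", plot,
                                       year))
    sp
  }
  for (cy in campaigns) {
    ws <- vapply(seq_len(n), function(i) {
      annual_water_stress(soil$clay[i], soil$silt[i], soil$sand[i],
                          soil$soil_depth[i],
                          crop = crop_of(sites$plot_id[i], cy),
                          year = cy, climate = climate)$stress_days
    }, numeric(1))
    soil[[paste0("water_stress_", cy)]] <- ws
  }

  indicators <- do.call(rbind, lapply(campaigns, function(cy) {
    practice_indicators(farm$operations, farm$applications, cy)
  }))

  # wide model table: one row per site, campaign-suffixed MV columns
  mt <- data.frame(site_id = sites$site_id,
                   forest = as.numeric(sites$land_use == "forest"),
                   clay = soil$clay, silt = soil$silt,
                   stringsAsFactors = FALSE)
  ind_cols <- c("crop_type", "Freq_winter", "Freq_spring", "Freq_summer",
                "Freq_brassi", "nbr_species", "tillage", "Freq_tillage",
                "Freq_plowing", "TFI_herbicide", "TFI_fungicide",
                "TFI_total", "N", "P", "K", "Mg", "S")
  for (cy in campaigns) {
    sfx <- paste0("_", cy)
    for (v in c("SOC", "TN", "pH", "water_stress")) {
      mt[[paste0(v, sfx)]] <- soil[[paste0(v, sfx)]]
    }
    icy <- indicators[indicators$sampling_year == cy, , drop = FALSE]
    idx <- match(sites$plot_id, icy$plot_id)
    for (v in ind_cols) {
      val <- icy[[v]][idx]
      if (v == "crop_type") {
        val[is.na(val)] <- "other"
      } else if (v == "tillage") {
        val[is.na(val)] <- "none"
      } else {
        val[is.na(val)] <- 0   # forest plots: no cropping operations
      }
      mt[[paste0(v, sfx)]] <- val
    }
    mt[[paste0("winter_crop", sfx)]] <-
      as.numeric(mt[[paste0("crop_type", sfx)]] == "winter")
  }

  resp_b <- simulate_responses(mt, truth, seed = seed + 5000L)
  resp_r <- simulate_responses(mt, richness_truth, seed = seed + 6000L)
  mt <- cbind(mt, resp_b$responses, resp_r$responses)

  campaign_table <- do.call(rbind, lapply(campaigns, function(cy) {
    sfx <- paste0("_", cy)
    suffixed <- grep(paste0(sfx, "$"), names(mt), value = TRUE)
    out <- data.frame(site_id = sites$site_id, campaign = cy,
                      x = sites$x, y = sites$y,
                      land_use = sites$land_use,
                      plot_id = sites$plot_id,
                      clay = soil$clay, silt = soil$silt, sand = soil$sand,
                      soil_depth = soil$soil_depth,
                      stringsAsFactors = FALSE)
    for (cl in suffixed) out[[sub(sfx, "", cl)]] <- mt[[cl]]
    out$CN <- out$SOC / out$TN
    out$OM <- om_from_soc(out$SOC)
    out
  }))

  structure(list(sites = sites, soil = soil, climate = climate,
                 operations = farm$operations,
                 applications = farm$applications,
                 traits = farm$traits,
                 indicators = indicators,
                 model_table = mt,
                 campaign_table = campaign_table,
                 scores = list(smmb = resp_b$scores,
                               richness = resp_r$scores),
                 truth = truth, richness_truth = richness_truth,
                 seed = seed),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(
    "Synthetic landscape: %d sites (%d forest), %d plot-years, seed %d\n",
    nrow(x$sites), sum(x$sites$land_use == "forest"),
    nrow(x$operations), x$seed))
  invisible(x)
}
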