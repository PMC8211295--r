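#' Default crop classification map
#'
#' Species -> crop class used by the rotation indicators. Brassicaceae takes
#' precedence over sowing season (it is its own class); "other" covers
#' fallow and perennials.
#'
#' @return data.frame with `species`, `crop_type`.
#' @export
default_crop_classes <- function() {
  data.frame(
    species = c("winter_wheat", "winter_barley", "triticale", "rye",
                "rapeseed", "mustard",
                "maize", "sunflower",
                "pea", "spring_barley",
                "fallow", "blackcurrant", "miscanthus"),
    crop_type = c("winter", "winter", "winter", "winter",
                  "brassicaceae", "brassicaceae",
                  "summer", "summer",
                  "spring", "spring",
                  "other", "other", "other"),
    stringsAsFactors = FALSE
  )
}

#' Farming-year boundaries
#'
#' Farming years run from 1 September to 31 August and are labelled by the
#' ending calendar year (the sampling year); the interval is half-open
#' `[Sept 1 of year-1, Sept 1 of year)`.
#'
#' @param year Farming year label.
#' @return List with `from` and `to` (`to` exclusive), both `Date`.
#' @export
farming_year_bounds <- function(year) {
  list(from = as.Date(sprintf("%d-09-01", year - 1L)),
       to = as.Date(sprintf("%d-09-01", year)))
}

#' Slice dated event records to one farming year
#'
#' @param events data.frame with a `date` column (`Date`).
#' @param sampling_year Farming year label (ending calendar year).
#' @return The rows whose dates fall in the half-open farming year.
#' @export
farming_year_slice <- function(events, sampling_year) {
  if (!"date" %in% names(events)) stop("events must have a `date` column")
  b <- farming_year_bounds(sampling_year)
  events[events$date >= b$from & events$date < b$to, , drop = FALSE]
}

#' Treatment frequency indices from pesticide applications
#'
#' TFI per category is the sum over applications of applied dose divided by
#' recommended dose; the total sums herbicide, fungicide, insecticide and
#' anti-slug treatments.
#'
#' @param applications data.frame with `category` (one of "herbicide",
#'   "fungicide", "insecticide", "anti_slug"), `applied_dose`,
#'   `recommended_dose` (> 0). Zero rows give all-zero TFIs.
#' @return Named list: `TFI_herbicide`, `TFI_fungicide`, `TFI_insecticide`,
#'   `TFI_anti_slug`, `TFI_total`.
#' @export
tfi <- function(applications) {
  cats <- c("herbicide", "fungicide", "insecticide", "anti_slug")
  if (nrow(applications) == 0L) {
    out <- as.list(stats::setNames(rep(0, 4), paste0("TFI_", cats)))
    out$TFI_total <- 0
    return(out)
  }
  if (any(!applications$category %in% cats)) {
    stop("unknown pesticide category: ",
         paste(setdiff(applications$category, cats), collapse = ", "))
  }
  if (any(!is.finite(applications$recommended_dose)) ||
      any(applications$recommended_dose <= 0)) {
    stop("recommended_dose must be > 0 for every application")
  }
  if (any(applications$applied_dose < 0)) stop("applied_dose must be >= 0")
  ratio <- applications$applied_dose / applications$recommended_dose
  by_cat <- vapply(cats, function(ct) sum(ratio[applications$category == ct]),
                   numeric(1))
  out <- as.list(stats::setNames(by_cat, paste0("TFI_", cats)))
  out$TFI_total <- sum(by_cat)
  out
}

#' Organic matter from organic carbon
#'
#' OM = 1.72 x SOC (the conventional Van Bemmelen factor), g/kg in, g/kg
#' out.
#'
#' @param soc Soil organic carbon (g/kg), >= 0.
#' @return Organic matter (g/kg).
#' @export
om_from_soc <- function(soc) {
  if (any(soc < 0)) stop("SOC must be >= 0")
  1.72 * soc
}

window_years <- function(sampling_year, len) {
  seq(sampling_year - len + 1L, sampling_year)
}

fetch_plot_years <- function(operations, plot, years) {
  rows <- operations[operations$plot_id == plot &
                       operations$farming_year %in% years, , drop = FALSE]
  if (length(unique(rows$farming_year)) != length(years)) {
    missing <- setdiff(years, rows$farming_year)
    stop(sprintf("plot %s: missing farming year(s) %s",
                 plot, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(rows$farming_year)) {
    stop(sprintf("plot %s: more than one crop in a farming year", plot))
  }
  rows[order(rows$farming_year), , drop = FALSE]
}

#' Crop-rotation indicators for one plot
#'
#' Six indicators: the sampling year's crop class, the class frequencies
#' (winter/spring/summer/Brassicaceae) over the 4 farming years ending at
#' the sampling year, and the number of distinct species over the 8 farming
#' years ending at the sampling year (fallow years are not counted as a
#' species).
#'
#' @param operations data.frame with one row per plot-year: `plot_id`,
#'   `farming_year`, `species`, `crop_type`.
#' @param plot Plot identifier.
#' @param sampling_year Campaign year.
#' @param crop_classes Species -> class map; used to fill `crop_type` when
#'   absent.
#' @return One-row data.frame with `crop_type`, `Freq_winter`,
#'   `Freq_spring`, `Freq_summer`, `Freq_brassi`, `nbr_species`.
#' @export
rotation_indicators <- function(operations, plot, sampling_year,
                                crop_classes = default_crop_classes()) {
  if (!"crop_type" %in% names(operations)) {
    operations$crop_type <-
      crop_classes$crop_type[match(operations$species, crop_classes$species)]
  }
  w4 <- fetch_plot_years(operations, plot, window_years(sampling_year, 4L))
  w8 <- fetch_plot_years(operations, plot, window_years(sampling_year, 8L))
  freq <- function(class) mean(w4$crop_type == class)
  species8 <- setdiff(unique(w8$species), "fallow")
  data.frame(
    plot_id = plot,
    crop_type = w4$crop_type[w4$farming_year == sampling_year],
    Freq_winter = freq("winter"),
    Freq_spring = freq("spring"),
    Freq_summer = freq("summer"),
    Freq_brassi = freq("brassicaceae"),
    nbr_species = length(species8),
    stringsAsFactors = FALSE
  )
}

#' Farming-intensity indicators for one plot
#'
#' Eleven indicators: the sampling year's tillage category; tillage and
#' plowing frequencies over the 4-year window (Freq_tillage counts any
#' soil-disturbing operation, i.e. intermediate, decompacting or plowing);
#' TFIs for the sampling farming year; and the fertilizer totals
#' (N, P, K, Mg, S, kg/ha/y) of the sampling farming year.
#'
#' @param operations One row per plot-year: `plot_id`, `farming_year`,
#'   `tillage` (one of "none", "intermediate", "decompacting", "plowing"),
#'   fertilizer columns `N`, `P`, `K`, `Mg`, `S`.
#' @param applications Pesticide application events: `plot_id`, `date`,
#'   `category`, `applied_dose`, `recommended_dose`.
#' @param plot Plot identifier.
#' @param sampling_year Campaign year.
#' @return One-row data.frame with the 11 indicators.
#' @export
intensity_indicators <- function(operations, applications, plot,
                                 sampling_year) {
  w4 <- fetch_plot_years(operations, plot, window_years(sampling_year, 4L))
  bad <- setdiff(w4$tillage,
                 c("none", "intermediate", "decompacting", "plowing"))
  if (length(bad) > 0) stop("unknown tillage category: ",
                            paste(bad, collapse = ", "))
  this <- w4[w4$farming_year == sampling_year, , drop = FALSE]
  apps <- applications[applications$plot_id == plot, , drop = FALSE]
  apps <- farming_year_slice(apps, sampling_year)
  tf <- tfi(apps)
  data.frame(
    plot_id = plot,
    tillage = this$tillage,
    Freq_tillage = mean(w4$tillage != "none"),
    Freq_plowing = mean(w4$tillage == "plowing"),
    TFI_herbicide = tf$TFI_herbicide,
    TFI_fungicide = tf$TFI_fungicide,
    TFI_total = tf$TFI_total,
    N = this$N, P = this$P, K = this$K, Mg = this$Mg, S = this$S,
    stringsAsFactors = FALSE
  )
}

#' All 17 practice indicators for every cropland plot of a campaign
#'
#' Joins [rotation_indicators()] and [intensity_indicators()]; plots with
#' incomplete history are excluded with a warning (mirroring the exclusion
#' of sites with incomplete farming management data).
#'
#' @param operations Plot-year table (see [intensity_indicators()]).
#' @param applications Pesticide event table.
#' @param sampling_year Campaign year.
#' @param crop_classes Species -> class map.
#' @return data.frame, one row per plot with complete history.
#' @export
practice_indicators <- function(operations, applications, sampling_year,
                                crop_classes = default_crop_classes()) {
  plots <- unique(operations$plot_id)
  rows <- lapply(plots, function(p) {
    tryCatch({
      rot <- rotation_indicators(operations, p, sampling_year, crop_classes)
      intens <- intensity_indicators(operations, applications, p,
                                     sampling_year)
      cbind(rot, intens[, setdiff(names(intens), "plot_id"), drop = FALSE],
            sampling_year = sampling_year)
    }, error = function(e) {
      warning(sprintf("plot %s excluded: %s", p, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
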