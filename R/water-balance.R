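#' Default pedotransfer table (texture class -> available water per cm)
#'
#' Available water-holding capacity per centimetre of soil, by texture
#' class, in mm/cm. Values are typical of the French texture-triangle
#' pedotransfer tables used for regional water-balance work; the table is an
#' editable data.frame so local calibrations can be substituted.
#'
#' @return data.frame with columns `texture_class`, `awc_mm_per_cm`.
#' @export
default_pedotransfer <- function() {
  data.frame(
    texture_class = c("sand", "loamy_sand", "sandy_loam", "loam",
                      "silt", "silt_loam", "sandy_clay_loam", "clay_loam",
                      "silty_clay_loam", "sandy_clay", "silty_clay", "clay"),
    awc_mm_per_cm = c(0.7, 1.0, 1.4, 1.8,
                      2.1, 2.0, 1.5, 1.8,
                      1.9, 1.4, 1.7, 1.6),
    stringsAsFactors = FALSE
  )
}

#' Classify a soil texture into a texture class
#'
#' Simplified texture-triangle rules over clay/silt/sand percentages of fine
#' earth (summing to 100 within 0.5).
#'
#' @param clay,silt,sand Percentages.
#' @return A texture class name present in [default_pedotransfer()].
#' @export
classify_texture <- function(clay, silt, sand) {
  total <- clay + silt + sand
  if (abs(total - 100) > 0.5) {
    stop(sprintf("texture must sum to 100 +- 0.5 (got %.2f)", total))
  }
  if (any(c(clay, silt, sand) < 0)) stop("texture fractions must be >= 0")
  if (clay >= 40) {
    if (silt >= 40) return("silty_clay")
    if (sand >= 45) return("sandy_clay")
    return("clay")
  }
  if (clay >= 27) {
    if (sand > 45) return("sandy_clay_loam")
    if (sand <= 20) return("silty_clay_loam")
    return("clay_loam")
  }
  if (silt >= 80 && clay < 12) return("silt")
  if (silt >= 50) return("silt_loam")
  if (clay >= 20 && sand > 45) return("sandy_clay_loam")
  if (silt + 1.5 * clay < 15) return("sand")
  if (silt + 2 * clay < 30) return("loamy_sand")
  if (clay >= 7 && sand <= 52 && silt >= 28) return("loam")
  "sandy_loam"
}

#' Water-holding capacity of the two soil compartments
#'
#' WHC1 covers the sampled 0-20 cm layer, WHC2 the rest of the profile
#' (20 cm to `soil_depth`). Each is the texture class's available water per
#' cm times the layer thickness.
#'
#' @param clay,silt,sand Texture percentages.
#' @param soil_depth Profile depth (cm).
#' @param pedotransfer Pedotransfer table (see [default_pedotransfer()]).
#' @return A list: `WHC1`, `WHC2` (mm), `texture_class`, `awc_mm_per_cm`.
#' @export
compute_whc <- function(clay, silt, sand, soil_depth,
                        pedotransfer = default_pedotransfer()) {
  if (soil_depth <= 0) stop("soil_depth must be positive")
  cls <- classify_texture(clay, silt, sand)
  row <- pedotransfer[pedotransfer$texture_class == cls, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("texture class '%s' missing from the pedotransfer table",
                 cls))
  }
  awc <- row$awc_mm_per_cm
  if (soil_depth < 20) {
    warning("soil profile shallower than 20 cm: WHC2 = 0")
    return(list(WHC1 = awc * soil_depth, WHC2 = 0,
                texture_class = cls, awc_mm_per_cm = awc))
  }
  list(WHC1 = awc * 20, WHC2 = awc * (soil_depth - 20),
       texture_class = cls, awc_mm_per_cm = awc)
}

#' Maximum crop evapotranspiration
#'
#' `ETM = Kc * ETPp`: the crop coefficient Kc scales Penman potential
#' evapotranspiration to the crop's stage-specific maximum.
#'
#' @param kc Crop coefficient (dimensionless, >= 0).
#' @param etpp Potential evapotranspiration (mm/day, >= 0).
#' @return ETM in mm/day.
#' @export
crop_etm <- function(kc, etpp) {
  if (any(kc < 0)) stop("Kc must be >= 0")
  if (any(etpp < 0)) stop("ETPp must be >= 0")
  kc * etpp
}

#' Run the daily two-compartment bucket model
#'
#' Each day, in order: (1) actual evapotranspiration `min(ETM, S1 + S2)` is
#' withdrawn, exhausting the topsoil store S1 before S2; (2) rainfall refills
#' S1 up to WHC1, overflow refills S2 up to WHC2, the remainder is lost;
#' (3) the day is flagged as a water-stress day iff the end-of-day topsoil
#' store S1 is empty (tolerance 1e-9 mm). Stores start at full capacity
#' unless `S1`/`S2` are given.
#'
#' @param RR Daily rainfall (mm), no missing days.
#' @param ETM Daily maximum crop evapotranspiration (mm), same length.
#' @param WHC1,WHC2 Compartment capacities (mm).
#' @param S1,S2 Initial storages (default: full).
#' @return A list: `trace` (data.frame with S1, S2, aet, loss, stress per
#'   day) and `stress_days` (total count).
#' @export
run_bucket <- function(RR, ETM, WHC1, WHC2, S1 = WHC1, S2 = WHC2) {
  if (length(RR) != length(ETM)) stop("RR and ETM must be the same length")
  if (any(RR < 0) || any(ETM < 0)) stop("RR and ETM must be >= 0")
  if (WHC1 < 0 || WHC2 < 0 || S1 < 0 || S2 < 0 || S1 > WHC1 || S2 > WHC2) {
    stop("invalid storage initialization")
  }
  nd <- length(RR)
  tS1 <- tS2 <- aet <- loss <- numeric(nd)
  stress <- logical(nd)
  tol <- 1e-9
  for (i in seq_len(nd)) {
    et <- min(ETM[i], S1 + S2)
    take1 <- min(et, S1)
    S1 <- S1 - take1
    S2 <- S2 - (et - take1)
    fill1 <- min(RR[i], WHC1 - S1)
    S1 <- S1 + fill1
    fill2 <- min(RR[i] - fill1, WHC2 - S2)
    S2 <- S2 + fill2
    tS1[i] <- S1
    tS2[i] <- S2
    aet[i] <- et
    loss[i] <- RR[i] - fill1 - fill2
    stress[i] <- S1 <= tol
  }
  list(trace = data.frame(S1 = tS1, S2 = tS2, aet = aet, loss = loss,
                          stress = stress),
       stress_days = sum(stress))
}

#' Kc lookup for a day of the farming year
#'
#' Farming years run 1 September to 31 August; Kc schedules give one value
#' per 10-day period of that year (days 1-10 are period 1, etc.; the last
#' period absorbs the remainder).
#'
#' @param dates Vector of `Date`s.
#' @param kc_values Numeric vector of per-period Kc (typically length 37).
#' @return Kc per date.
#' @export
kc_for_dates <- function(dates, kc_values) {
  fy_start <- as.Date(sprintf("%d-09-01",
                              ifelse(as.integer(format(dates, "%m")) >= 9,
                                     as.integer(format(dates, "%Y")),
                                     as.integer(format(dates, "%Y")) - 1L)))
  doy <- as.integer(dates - fy_start)          # 0-based day of farming year
  period <- pmin(doy %/% 10L + 1L, length(kc_values))
  kc_values[period]
}

#' Default FAO-style Kc schedules per crop
#'
#' 37 ten-day periods covering the farming year (Sept-Aug). Shapes follow
#' the usual development / mid-season / late-season pattern of the FAO crop
#' coefficient tables; `forest` uses a constant 1.0 and `fallow` a low bare
#' soil/cover value.
#'
#' @return Named list of numeric vectors (length 37).
#' @export
default_kc_schedules <- function() {
  ramp <- function(pts) {
    # pts: list of c(period, kc) knots, linearly interpolated over 1..37
    x <- vapply(pts, `[`, numeric(1), 1)
    y <- vapply(pts, `[`, numeric(1), 2)
    stats::approx(x, y, xout = 1:37, rule = 2)$y
  }
  list(
    winter_wheat  = ramp(list(c(1, 0.3), c(4, 0.7), c(20, 0.9), c(26, 1.15),
                              c(31, 1.15), c(34, 0.4), c(37, 0.3))),
    winter_barley = ramp(list(c(1, 0.3), c(4, 0.7), c(20, 0.9), c(25, 1.1),
                              c(30, 1.1), c(33, 0.35), c(37, 0.3))),
    triticale     = ramp(list(c(1, 0.3), c(4, 0.7), c(20, 0.9), c(26, 1.1),
                              c(31, 1.1), c(34, 0.4), c(37, 0.3))),
    rye           = ramp(list(c(1, 0.3), c(4, 0.65), c(20, 0.85), c(26, 1.05),
                              c(31, 1.05), c(34, 0.4), c(37, 0.3))),
    rapeseed      = ramp(list(c(1, 0.35), c(3, 0.8), c(20, 1.0), c(26, 1.1),
                              c(30, 1.1), c(33, 0.4), c(37, 0.3))),
    mustard       = ramp(list(c(1, 0.35), c(3, 0.7), c(20, 0.9), c(26, 1.05),
                              c(30, 1.05), c(33, 0.4), c(37, 0.3))),
    maize         = ramp(list(c(1, 0.3), c(23, 0.3), c(26, 0.6), c(29, 1.2),
                              c(33, 1.2), c(36, 0.5), c(37, 0.4))),
    sunflower     = ramp(list(c(1, 0.3), c(23, 0.3), c(26, 0.6), c(29, 1.1),
                              c(32, 1.1), c(35, 0.4), c(37, 0.35))),
    pea           = ramp(list(c(1, 0.3), c(19, 0.4), c(22, 0.8), c(26, 1.15),
                              c(29, 1.15), c(32, 0.35), c(37, 0.3))),
    spring_barley = ramp(list(c(1, 0.3), c(19, 0.4), c(22, 0.8), c(26, 1.1),
                              c(29, 1.1), c(32, 0.3), c(37, 0.3))),
    blackcurrant  = ramp(list(c(1, 0.5), c(20, 0.6), c(26, 1.0), c(32, 1.0),
                              c(36, 0.6), c(37, 0.5))),
    miscanthus    = ramp(list(c(1, 0.4), c(20, 0.5), c(26, 1.1), c(33, 1.1),
                              c(37, 0.5))),
    fallow        = rep(0.3, 37),
    forest        = rep(1.0, 37)
  )
}

#' Cumulative days of water stress for one site and farming year
#'
#' Composes [compute_whc()], the per-10-day Kc lookup and [run_bucket()]
#' over one farming year (1 Sept of `year - 1` to 31 Aug of `year`),
#' initializing both stores at capacity, and returns the annual stress-day
#' count (d/y).
#'
#' @param clay,silt,sand,soil_depth Site texture and profile depth.
#' @param crop Crop (or cover) name; must have a Kc schedule.
#' @param year Farming year, labelled by its ending calendar year.
#' @param climate data.frame with `date` (Date), `RR`, `ETPp` covering the
#'   farming year with no gaps.
#' @param kc_schedules Named list of Kc vectors (see
#'   [default_kc_schedules()]).
#' @param pedotransfer Pedotransfer table.
#' @return A list: `stress_days`, `WHC1`, `WHC2`, `trace`.
#' @export
annual_water_stress <- function(clay, silt, sand, soil_depth, crop, year,
                                climate,
                                kc_schedules = default_kc_schedules(),
                                pedotransfer = default_pedotransfer()) {
  if (!crop %in% names(kc_schedules)) {
    stop(sprintf("no Kc schedule for crop '%s' (farming year %d)",
                 crop, year))
  }
  from <- as.Date(sprintf("%d-09-01", year - 1L))
  to <- as.Date(sprintf("%d-08-31", year))
  cl <- climate[climate$date >= from & climate$date <= to, , drop = FALSE]
  cl <- cl[order(cl$date), , drop = FALSE]
  nd <- as.integer(to - from) + 1L
  if (nrow(cl) != nd || any(diff(cl$date) != 1)) {
    stop(sprintf("climate series incomplete for farming year %d", year))
  }
  whc <- compute_whc(clay, silt, sand, soil_depth, pedotransfer)
  kc <- kc_for_dates(cl$date, kc_schedules[[crop]])
  etm <- crop_etm(kc, cl$ETPp)
  res <- run_bucket(cl$RR, etm, whc$WHC1, whc$WHC2)
  list(stress_days = res$stress_days, WHC1 = whc$WHC1, WHC2 = whc$WHC2,
       trace = res$trace)
}
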