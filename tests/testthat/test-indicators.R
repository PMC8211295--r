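toy_ops <- function() {
  # plot A: 8 farming years 2004-2011 with a classic cereal rotation
  data.frame(
    plot_id = "A",
    farming_year = 2004:2011,
    species = c("maize", "pea", "winter_wheat", "sunflower",
                "winter_wheat", "winter_wheat", "winter_barley",
                "rapeseed"),
    tillage = c("plowing", "plowing", "intermediate", "plowing",
                "plowing", "intermediate", "none", "decompacting"),
    N = 100, P = 50, K = 30, Mg = 5, S = 20,
    stringsAsFactors = FALSE
  )
}

test_that("farming-year slice uses the half-open September boundary", {
  ev <- data.frame(date = as.Date(c("2010-10-05", "2011-10-02",
                                    "2010-09-01", "2011-09-01",
                                    "2011-08-31")),
                   id = 1:5)
  got <- farming_year_slice(ev, 2011)
  expect_setequal(got$id, c(1L, 3L, 5L))
})

test_that("rotation indicators count classes over the 4-year window", {
  # window 2008-2011: wheat, wheat, barley, rapeseed
  rot <- rotation_indicators(toy_ops(), "A", 2011)
  expect_equal(rot$Freq_winter, 0.75)
  expect_equal(rot$Freq_brassi, 0.25)
  expect_equal(rot$Freq_spring, 0)
  expect_equal(rot$Freq_summer, 0)
  expect_identical(rot$crop_type, "brassicaceae")
  # 8-year species count: maize, pea, wheat, sunflower, barley, rapeseed
  expect_identical(rot$nbr_species, 6L)
})

test_that("a monoculture has frequency one and a single species", {
  ops <- data.frame(plot_id = "M", farming_year = 2004:2011,
                    species = "winter_wheat", tillage = "plowing",
                    N = 0, P = 0, K = 0, Mg = 0, S = 0,
                    stringsAsFactors = FALSE)
  rot <- rotation_indicators(ops, "M", 2011)
  expect_equal(rot$Freq_winter, 1)
  expect_equal(rot$Freq_spring + rot$Freq_summer + rot$Freq_brassi, 0)
  expect_identical(rot$nbr_species, 1L)
})

test_that("fallow years are not counted as rotation species", {
  ops <- toy_ops()
  ops$species[1] <- "fallow"
  rot <- rotation_indicators(ops, "A", 2011)
  expect_identical(rot$nbr_species, 5L)
})

test_that("class frequencies over a complete window sum to one", {
  set.seed(51)
  cls <- default_crop_classes()
  for (i in 1:10) {
    sp <- sample(cls$species, 8, replace = TRUE)
    ops <- data.frame(plot_id = "R", farming_year = 2004:2011,
                      species = sp, tillage = "none",
                      N = 0, P = 0, K = 0, Mg = 0, S = 0,
                      stringsAsFactors = FALSE)
    rot <- rotation_indicators(ops, "R", 2011)
    w4 <- ops$species[ops$farming_year >= 2008]
    other <- mean(cls$crop_type[match(w4, cls$species)] == "other")
    expect_equal(rot$Freq_winter + rot$Freq_spring + rot$Freq_summer +
                   rot$Freq_brassi + other, 1)
  }
})

test_that("TFI sums dose ratios per category and in total", {
  apps <- data.frame(category = c("herbicide", "herbicide", "fungicide"),
                     applied_dose = c(0.5, 0.5, 1),
                     recommended_dose = c(1, 1, 1))
  t1 <- tfi(apps)
  expect_equal(t1$TFI_herbicide, 1.0)
  expect_equal(t1$TFI_fungicide, 1.0)
  expect_equal(t1$TFI_total, 2.0)
  one <- tfi(data.frame(category = "insecticide", applied_dose = 2,
                        recommended_dose = 2))
  expect_equal(one$TFI_total, 1.0)
  none <- tfi(data.frame(category = character(0), applied_dose = numeric(0),
                         recommended_dose = numeric(0)))
  expect_equal(none$TFI_total, 0)
  expect_error(tfi(data.frame(category = "herbicide", applied_dose = 1,
                              recommended_dose = 0)), "> 0")
})

test_that("TFI is additive over disjoint application lists", {
  set.seed(52)
  apps <- data.frame(
    category = sample(c("herbicide", "fungicide", "insecticide",
                        "anti_slug"), 12, replace = TRUE),
    applied_dose = runif(12, 0.2, 1.5),
    recommended_dose = runif(12, 0.8, 1.2))
  whole <- tfi(apps)$TFI_total
  parts <- tfi(apps[1:5, ])$TFI_total + tfi(apps[6:12, ])$TFI_total
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("intensity indicators count tillage over the window", {
  ops <- toy_ops()
  # window 2008-2011: plowing, intermediate, none, decompacting
  apps <- data.frame(plot_id = "A", date = as.Date("2011-04-01"),
                     category = "herbicide", applied_dose = 1,
                     recommended_dose = 1)
  ind <- intensity_indicators(ops, apps, "A", 2011)
  expect_equal(ind$Freq_plowing, 0.25)
  expect_equal(ind$Freq_tillage, 0.75)
  expect_identical(ind$tillage, "decompacting")
  expect_equal(ind$TFI_herbicide, 1)
  expect_equal(ind$TFI_total, 1)
  # all-plowing and no-till extremes
  ops$tillage <- "plowing"
  ind2 <- intensity_indicators(ops, apps, "A", 2011)
  expect_equal(ind2$Freq_plowing, 1)
  expect_equal(ind2$Freq_tillage, 1)
  ops$tillage <- "none"
  ind3 <- intensity_indicators(ops, apps, "A", 2011)
  expect_equal(ind3$Freq_plowing, 0)
  expect_equal(ind3$Freq_tillage, 0)
})

test_that("indicators are invariant to log row order", {
  ops <- toy_ops()
  set.seed(53)
  shuffled <- ops[sample.int(nrow(ops)), ]
  expect_equal(rotation_indicators(ops, "A", 2011),
               rotation_indicators(shuffled, "A", 2011))
})

test_that("incomplete history names the offending plot", {
  ops <- toy_ops()[-3, ]  # drop 2006
  expect_error(rotation_indicators(ops, "A", 2011), "A.*2006")
  apps <- data.frame(plot_id = character(0), date = as.Date(character(0)),
                     category = character(0), applied_dose = numeric(0),
                     recommended_dose = numeric(0))
  expect_warning(practice_indicators(ops, apps, 2011), "excluded")
})

test_that("organic matter is 1.72 times organic carbon", {
  expect_identical(om_from_soc(0), 0)
  expect_equal(om_from_soc(10), 17.2)
  expect_equal(round(om_from_soc(21.39), 2), 36.79)
  expect_error(om_from_soc(-1), ">= 0")
})
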