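test_that("sampling design: clipped grid plus random sites with minimum spacing", {
  s <- make_sites(grid_spacing = 215, extent = c(3000, 4000),
                  n_random = 30, n_retain = NULL, forest_fraction = 0.16,
                  seed = 7)
  # 13 x 18 grid candidates fit a 3000 x 4000 extent at 215-m spacing
  expect_identical(nrow(s), 13L * 18L + 30L)
  d <- dist(cbind(s$x, s$y))
  expect_gte(min(d), 30)
  expect_false(anyDuplicated(s[, c("x", "y")]) > 0)
})

test_that("no random sites and zero forest fraction give a pure cropland grid", {
  s <- make_sites(grid_spacing = 215, extent = c(1000, 1000),
                  n_random = 0, n_retain = NULL, forest_fraction = 0,
                  seed = 1)
  expect_identical(nrow(s), 16L)  # 4 x 4
  expect_true(all(s$land_use == "cropland"))
})

test_that("default design retains 269 sites with a contiguous forest block", {
  s <- make_sites(seed = 5)
  expect_identical(nrow(s), 269L)
  nf <- sum(s$land_use == "forest")
  expect_true(abs(nf - 43) <= 8)
  # contiguity proxy: forest sites are mutually closer than average
  f <- s[s$land_use == "forest", ]
  expect_lt(mean(dist(cbind(f$x, f$y))), mean(dist(cbind(s$x, s$y))))
  # land use is constant within a plot
  expect_true(all(tapply(s$land_use, s$plot_id,
                         function(x) length(unique(x))) == 1))
})

test_that("site generation is reproducible and honors impossible configurations", {
  expect_identical(make_sites(seed = 3), make_sites(seed = 3))
  expect_false(identical(make_sites(seed = 3), make_sites(seed = 4)))
  expect_error(make_sites(grid_spacing = 100, extent = c(150, 150),
                          n_random = 500, n_retain = NULL, seed = 1),
               "minimum inter-site distance")
  expect_error(make_sites(grid_spacing = 20, extent = c(100, 100),
                          min_dist = 30, seed = 1), "exceeds")
})

test_that("soil fields honor their specs in the degenerate limits", {
  s <- make_sites(grid_spacing = 215, extent = c(1500, 1500),
                  n_random = 10, n_retain = NULL, forest_fraction = 0.2,
                  seed = 9)
  f <- simulate_soil_fields(s, list(
    const = list(model = matern_variogram(0, 1, 100), mean = 5, sd = 0),
    offset = list(model = matern_variogram(0, 1, 100), mean = 0, sd = 0,
                  forest_offset = 2)), seed = 1)
  expect_true(all(f$const == 5))
  expect_equal(sort(unique(f$offset)), c(0, 2))
  expect_identical(f$offset == 2, s$land_use == "forest")
})

test_that("a vanishing range produces spatially unstructured fields", {
  s <- make_sites(grid_spacing = 215, extent = c(2000, 2000),
                  n_random = 0, n_retain = NULL, forest_fraction = 0,
                  seed = 2)
  f <- simulate_soil_fields(s, list(
    wn = list(model = matern_variogram(0, 1, 1e-6), mean = 0, sd = 1)),
    seed = 3)
  ev <- suppressWarnings(
    empirical_variogram(cbind(s$x, s$y), f$wn, n_bins = 6))
  expect_true(max(abs(ev$gamma - var(f$wn))) < 0.5 * var(f$wn))
})

test_that("simulated fields carry the assumed covariance range", {
  # repeated draws from an exponential model recover the range within 50%
  set.seed(61)
  s <- make_sites(grid_spacing = 215, extent = c(3225, 3440),
                  n_random = 30, n_retain = 200, forest_fraction = 0,
                  seed = 61)
  spec <- list(f = list(model = matern_variogram(0, 1, 150, 0.5),
                        mean = 0, sd = 1))
  ranges <- vapply(1:8, function(i) {
    f <- simulate_soil_fields(s, spec, seed = 100 + i)
    ev <- suppressWarnings(empirical_variogram(cbind(s$x, s$y), f$f))
    ft <- fit_matern(ev, kappa_grid = 0.5)
    ft$model$range
  }, numeric(1))
  expect_lt(abs(median(ranges) - 150) / 150, 0.5)
})

test_that("texture closure always sums to 100", {
  set.seed(62)
  tex <- close_texture(rnorm(50, 33, 15), rnorm(50, 56, 15),
                       rnorm(50, 9, 15))
  expect_true(all(abs(rowSums(tex) - 100) < 1e-9))
  expect_true(all(tex >= 0))
})

test_that("farm history is reproducible and a one-crop menu is degenerate", {
  plots <- data.frame(plot_id = c("P1", "P2"),
                      land_use = c("cropland", "cropland"))
  menu <- data.frame(species = "winter_wheat", weight = 1,
                     winter_cereal = TRUE, minor_winter = FALSE,
                     spring_summer = FALSE, stringsAsFactors = FALSE)
  fh <- simulate_farm_history(plots, years = 2004:2011, menu = menu,
                              seed = 4)
  expect_true(all(fh$operations$species == "winter_wheat"))
  rot <- rotation_indicators(fh$operations, "P1", 2011)
  expect_equal(rot$Freq_winter, 1)
  expect_identical(simulate_farm_history(plots, seed = 8)$operations,
                   simulate_farm_history(plots, seed = 8)$operations)
})

test_that("without drift the two campaigns' practices are exchangeable", {
  # pooled over seeds, the campaign TFI distributions should not differ
  plots <- data.frame(plot_id = sprintf("P%02d", 1:12),
                      land_use = "cropland")
  t11 <- t16 <- c()
  for (s in 1:20) {
    fh <- simulate_farm_history(plots, years = 2004:2016, drift = FALSE,
                                seed = s)
    for (cy in c(2011, 2016)) {
      ind <- suppressWarnings(
        practice_indicators(fh$operations, fh$applications, cy))
      if (cy == 2011) t11 <- c(t11, ind$TFI_total)
      else t16 <- c(t16, ind$TFI_total)
    }
  }
  expect_gt(wilcox.test(t11, t16)$p.value, 0.01)
})

test_that("with drift plowing recedes and pesticide pressure rises", {
  plots <- data.frame(plot_id = sprintf("P%02d", 1:25),
                      land_use = "cropland")
  fh <- simulate_farm_history(plots, years = 2004:2016, drift = TRUE,
                              seed = 10)
  i11 <- suppressWarnings(
    practice_indicators(fh$operations, fh$applications, 2011))
  i16 <- suppressWarnings(
    practice_indicators(fh$operations, fh$applications, 2016))
  expect_gt(mean(i11$Freq_plowing), mean(i16$Freq_plowing))
  expect_lt(mean(i11$TFI_total), mean(i16$TFI_total))
})

test_that("responses propagate the true path coefficients exactly", {
  set.seed(63)
  n <- 269
  dat <- data.frame(a = rnorm(n))
  B <- matrix(c(0, 0.8, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  tr <- ground_truth(B, blocks = list(A = "a"),
                     response_mvs = list(B = list(b_obs = c(10, 2))),
                     noise_sd = 0)
  res <- simulate_responses(dat, tr, seed = 1)
  # a chain A -> B with beta = 0.8 leaves a sample correlation of 0.8
  expect_equal(cor(res$scores$A, res$scores$B), 0.8, tolerance = 1e-10)
  # regression on the realized scores recovers beta exactly
  expect_equal(unname(coef(lm(res$scores$B ~ res$scores$A))[2]), 0.8,
               tolerance = 1e-10)
  # emitted response is the affine image of the score (noise_sd = 0)
  expect_equal(res$responses$b_obs, 10 + 2 * res$scores$B,
               tolerance = 1e-12)
})

test_that("a null path structure leaves responses independent of predictors", {
  set.seed(64)
  n <- 300
  dat <- data.frame(a = rnorm(n))
  B <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  cors <- vapply(1:10, function(s) {
    tr <- ground_truth(B, blocks = list(A = "a"),
                       response_mvs = list(B = list(b = c(0, 1))),
                       noise_sd = 0)
    res <- simulate_responses(dat, tr, seed = s)
    cor(res$scores$A, res$responses$b)
  }, numeric(1))
  expect_lt(max(abs(cors)), 3.5 / sqrt(n))
})

test_that("a pure temporal arrow yields the stated lag correlation", {
  set.seed(65)
  dat <- data.frame(dummy = rnorm(269))
  lv <- c("resp_2011", "resp_2016")
  B <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(lv, lv))
  tr <- ground_truth(B, blocks = list(),
                     response_mvs = list(
                       resp_2011 = list(y_2011 = c(0, 1)),
                       resp_2016 = list(y_2016 = c(0, 1))),
                     noise_sd = 0)
  res <- simulate_responses(dat, tr, seed = 2)
  expect_equal(cor(res$scores$resp_2011, res$scores$resp_2016), 0.5,
               tolerance = 1e-10)
})

test_that("cyclic truth matrices are rejected", {
  lv <- c("A", "B")
  B <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(lv, lv))
  expect_error(ground_truth(B, list(A = "a"), list(), 0.1), "cyclic")
})

test_that("the full landscape is bit-identical under a repeated seed", {
  a <- simulate_landscape(seed = 11)
  b <- simulate_landscape(seed = 11)
  expect_identical(a$campaign_table, b$campaign_table)
  expect_identical(a$model_table, b$model_table)
  expect_identical(a$operations, b$operations)
})

test_that("campaign responses coincide when predictors match and noise is off", {
  # identical MV columns for the two campaigns + noise_sd = 0 =>
  # identical response values at every site (shared base residuals)
  set.seed(66)
  n <- 100
  base <- data.frame(soc = rnorm(n), stress = rnorm(n))
  dat <- data.frame(SOC_2011 = base$soc, SOC_2016 = base$soc,
                    stress_2011 = base$stress, stress_2016 = base$stress)
  lv <- c("res_2011", "res_2016", "resp_2011", "resp_2016")
  B <- matrix(0, 4, 4, dimnames = list(lv, lv))
  B["res_2011", "resp_2011"] <- 0.6
  B["res_2016", "resp_2016"] <- 0.6
  tr <- ground_truth(
    B,
    blocks = list(res_2011 = c("SOC_2011", "stress_2011"),
                  res_2016 = c("SOC_2016", "stress_2016")),
    response_mvs = list(resp_2011 = list(y_2011 = c(65, 35)),
                        resp_2016 = list(y_2016 = c(65, 35))),
    noise_sd = 0)
  res <- simulate_responses(dat, tr, seed = 3)
  expect_equal(res$responses$y_2011, res$responses$y_2016,
               tolerance = 1e-12)
})

test_that("landscape tables are structurally coherent", {
  land <- simulate_landscape(seed = 12)
  ct <- land$campaign_table
  expect_identical(nrow(ct), 2L * nrow(land$sites))
  expect_true(all(abs(ct$clay + ct$silt + ct$sand - 100) < 1e-9))
  expect_true(all(ct$water_stress >= 0))
  expect_equal(ct$OM, 1.72 * ct$SOC, tolerance = 1e-12)
  # forest plots have no cropping operations
  forest_sites <- ct$land_use == "forest"
  expect_true(all(ct$TFI_total[forest_sites] == 0))
  expect_true(all(ct$Freq_plowing[forest_sites] == 0))
})
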