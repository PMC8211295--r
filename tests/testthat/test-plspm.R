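# two correlated reflective blocks with a known inter-factor effect
factor_data <- function(n, beta = 0.6, lambda = 0.85, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n)
  f2 <- beta * f1 + sqrt(1 - beta^2) * rnorm(n)
  emit <- function(f, p) {
    sapply(seq_len(p), function(i) lambda * f +
             sqrt(1 - lambda^2) * rnorm(length(f)))
  }
  X <- emit(f1, 3)
  Y <- emit(f2, 3)
  d <- data.frame(X, Y)
  names(d) <- c("x1", "x2", "x3", "y1", "y2", "y3")
  d
}

test_that("Cronbach's alpha for two standardized items equals 2r/(1+r)", {
  set.seed(71)
  x <- rnorm(200)
  y <- 0.5 * x + rnorm(200)
  r <- cor(x, y)
  u <- unidimensionality(data.frame(x, y))
  expect_equal(u$alpha, 2 * r / (1 + r), tolerance = 1e-12)
})

test_that("unidimensionality hits its limits for perfect and null correlation", {
  x <- rnorm(500)
  perf <- unidimensionality(data.frame(a = x, b = 2 * x + 3))
  expect_equal(perf$alpha, 1, tolerance = 1e-12)
  expect_equal(perf$rho, 1, tolerance = 1e-12)
  expect_true(perf$pass)
  set.seed(72)
  indep <- unidimensionality(data.frame(a = rnorm(2000), b = rnorm(2000)))
  expect_lt(abs(indep$alpha), 0.15)
  expect_false(indep$pass)
  single <- unidimensionality(data.frame(a = rnorm(10)))
  expect_true(single$pass)
  expect_error(unidimensionality(data.frame(a = rnorm(5), b = rep(1, 5))),
               "zero-variance")
})

test_that("a two-block single-MV model reproduces the Pearson correlation", {
  set.seed(73)
  d <- data.frame(x = rnorm(80), y = rnorm(80))
  fit <- fit_plspm(d, two_block_spec())
  expect_equal(fit$path["X", "Y"], cor(d$x, d$y), tolerance = 1e-10)
  expect_equal(unname(fit$r2["Y"]), cor(d$x, d$y)^2, tolerance = 1e-10)
})

test_that("a single-MV chain reproduces the pairwise regression slopes", {
  set.seed(74)
  a <- rnorm(120)
  b <- 0.7 * a + rnorm(120, 0, 0.5)
  cc <- 0.5 * b + rnorm(120, 0, 0.8)
  d <- data.frame(a, b, cc)
  spec <- plspm_spec(list(plspm_block("A", "a"), plspm_block("B", "b"),
                          plspm_block("C", "cc")),
                     data.frame(from = c("A", "B"), to = c("B", "C")))
  fit <- fit_plspm(d, spec)
  expect_equal(fit$path["A", "B"], cor(a, b), tolerance = 1e-10)
  expect_equal(fit$path["B", "C"], cor(b, cc), tolerance = 1e-10)
  expect_equal(unname(fit$r2["C"]), cor(b, cc)^2, tolerance = 1e-10)
})

test_that("LV scores have unit variance and outputs are scale-invariant", {
  d <- factor_data(150, seed = 75)
  spec <- plspm_spec(list(plspm_block("F1", c("x1", "x2", "x3")),
                          plspm_block("F2", c("y1", "y2", "y3"))),
                     data.frame(from = "F1", to = "F2"))
  fit <- fit_plspm(d, spec)
  expect_equal(unname(apply(fit$scores, 2, sd)), c(1, 1),
               tolerance = 1e-12)
  d2 <- d
  d2$x2 <- d2$x2 * 1000  # positive rescaling of one MV
  fit2 <- fit_plspm(d2, spec)
  expect_equal(fit$path, fit2$path, tolerance = 1e-10)
  expect_equal(fit$loadings, fit2$loadings, tolerance = 1e-10)
  expect_equal(fit$gof, fit2$gof, tolerance = 1e-10)
})

test_that("all three inner weighting schemes agree on clean factor data", {
  d <- factor_data(200, seed = 76)
  paths <- data.frame(from = "F1", to = "F2")
  est <- vapply(c("centroid", "factorial", "path"), function(sc) {
    spec <- plspm_spec(list(plspm_block("F1", c("x1", "x2", "x3")),
                            plspm_block("F2", c("y1", "y2", "y3"))),
                       paths, scheme = sc)
    fit_plspm(d, spec)$path["F1", "F2"]
  }, numeric(1))
  expect_lt(max(est) - min(est), 0.01)
})

test_that("path coefficients recover a noise-free single-MV generating model", {
  land <- simulate_landscape(seed = 77, noise_sd = 0)
  mt <- land$model_table
  # every LV measured by exactly one MV: the PLS scores equal the
  # generator's scores and the coefficients are exact
  lv <- c("resources_2011", "habitat", "rotation_2011", "intensity_2011",
          "response_2011")
  B <- matrix(0, 5, 5, dimnames = list(lv, lv))
  B["resources_2011", "response_2011"] <- 0.45
  B["habitat", "response_2011"] <- 0.15
  B["rotation_2011", "response_2011"] <- -0.15
  B["intensity_2011", "response_2011"] <- -0.2
  tr <- ground_truth(B,
                     blocks = list(resources_2011 = "SOC_2011",
                                   habitat = "clay",
                                   rotation_2011 = "Freq_winter_2011",
                                   intensity_2011 = "TFI_total_2011"),
                     response_mvs = list(
                       response_2011 = list(resp = c(0, 1))),
                     noise_sd = 0)
  res <- simulate_responses(mt, tr, seed = 5)
  dat <- cbind(mt, res$responses)
  spec <- architecture_from_truth(tr)
  fit <- fit_plspm(dat, spec)
  nz <- which(B != 0, arr.ind = TRUE)
  expect_equal(fit$path[cbind(rownames(B)[nz[, 1]],
                              colnames(B)[nz[, 2]])],
               B[nz], tolerance = 1e-6)
})

test_that("measurement validation flags planted defects and passes clean data", {
  # weakly related factors: cross-loading diagnostics are informative
  # (with strongly correlated LVs a mis-wired MV is partly masked)
  d <- factor_data(300, beta = 0.25, seed = 78)
  clean <- plspm_spec(list(plspm_block("F1", c("x1", "x2", "x3")),
                           plspm_block("F2", c("y1", "y2", "y3"))),
                      data.frame(from = "F1", to = "F2"))
  expect_identical(nrow(validate_measurement(fit_plspm(d, clean))), 0L)
  # an MV wired into the wrong block cross-loads higher on its true LV
  # (the true home block must be in the model for the diagnostic to see it;
  # in a two-LV model mode-A weights cannot separate the blocks)
  set.seed(88)
  n <- 300
  f1 <- rnorm(n)
  f3 <- rnorm(n)
  f2 <- 0.4 * f1 + 0.4 * f3 + 0.6 * rnorm(n)
  lam <- function(f) 0.85 * f + sqrt(1 - 0.85^2) * rnorm(n)
  d3 <- data.frame(x1 = lam(f1), x2 = lam(f1), z1 = lam(f3),
                   y1 = lam(f2), y2 = lam(f2),
                   z2 = lam(f3), z3 = lam(f3))
  wrong <- plspm_spec(
    list(plspm_block("F1", c("x1", "x2", "z1")),
         plspm_block("F2", c("y1", "y2")),
         plspm_block("F3", c("z2", "z3"))),
    data.frame(from = c("F1", "F3"), to = c("F2", "F2")))
  v <- validate_measurement(fit_plspm(d3, wrong))
  expect_true("z1" %in% v$mv)
  # a sign-flipped MV shows a non-positive loading
  d2 <- d
  d2$x2 <- -d2$x2
  v2 <- validate_measurement(fit_plspm(d2, clean))
  expect_true(any(v2$mv == "x2" & v2$type == "non-positive loading"))
})

test_that("pruning removes exactly the planted junk MV, symmetrically", {
  set.seed(79)
  d <- factor_data(300, seed = 79)
  d$junk_2011 <- rnorm(300)
  d$junk_2016 <- rnorm(300)
  d$y1_2016 <- d$y1 + rnorm(300, 0, 0.3)  # paired-campaign response block
  spec <- plspm_spec(
    list(plspm_block("F1", c("x1", "x2", "x3")),
         plspm_block("resp_2011", c("y1", "y2", "junk_2011")),
         plspm_block("resp_2016", c("y1_2016", "y3", "junk_2016"))),
    data.frame(from = c("F1", "F1"), to = c("resp_2011", "resp_2016")))
  pr <- prune_model(d, spec)
  kept <- unlist(lapply(pr$spec$blocks, `[[`, "mvs"))
  expect_false(any(c("junk_2011", "junk_2016") %in% kept))
  expect_true(all(c("y1", "y2", "y1_2016", "y3") %in% kept))
  # a clean spec comes back unchanged
  clean <- plspm_spec(list(plspm_block("F1", c("x1", "x2", "x3")),
                           plspm_block("F2", c("y1", "y2", "y3"))),
                      data.frame(from = "F1", to = "F2"))
  pr2 <- prune_model(factor_data(300, seed = 80), clean)
  expect_identical(pr2$spec$blocks, clean$blocks)
  expect_identical(nrow(pr2$audit), 0L)
})

test_that("effects decompose exactly along chains and random DAGs", {
  lv <- c("A", "B", "C")
  B <- matrix(0, 3, 3, dimnames = list(lv, lv))
  B["A", "B"] <- 0.5
  B["B", "C"] <- 0.4
  eff <- effects_decomposition(B)
  expect_equal(eff$direct["A", "C"], 0)
  expect_equal(eff$indirect["A", "C"], 0.2, tolerance = 1e-12)
  expect_equal(eff$total["A", "C"], 0.2, tolerance = 1e-12)
  single <- matrix(c(0, 0.7, 0, 0), 2, 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(all(effects_decomposition(single)$indirect == 0))
  # random upper-triangular 5-LV DAGs against exhaustive path enumeration
  set.seed(81)
  for (i in 1:10) {
    K <- 5
    M <- matrix(0, K, K, dimnames = list(letters[1:K], letters[1:K]))
    M[upper.tri(M)] <- rbinom(10, 1, 0.6) * runif(10, -0.8, 0.8)
    eff <- effects_decomposition(M)
    expect_equal(eff$total, enum_total_effects(M), tolerance = 1e-12)
    expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-15)
  }
  cyc <- matrix(c(0, 1, 1, 0), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(effects_decomposition(cyc), "nilpotent")
})

test_that("GOF combines communality and R2 with the stated quality labels", {
  set.seed(82)
  x <- rnorm(60)
  d <- data.frame(x = x, y = x)  # R2 = 1, communalities = 1
  g <- gof(fit_plspm(d, two_block_spec()))
  expect_equal(g$gof, 1, tolerance = 1e-10)
  expect_identical(g$label, "very good")
  # boundary: GOF exactly 0.4 is not strictly greater, hence "poor"
  fake <- structure(list(communality = c(0.64, 0.64),
                         r2 = c(Y = 0.25),
                         spec = list(endogenous = "Y")),
                    class = "plspm_fit")
  gb <- gof(fake)
  expect_equal(gb$gof, 0.4, tolerance = 1e-12)
  expect_identical(gb$label, "poor")
  # single-MV blocks: GOF reduces to sqrt(mean R2)
  d2 <- data.frame(x = rnorm(100))
  d2$y <- 0.6 * d2$x + rnorm(100, 0, 0.8)
  fit2 <- fit_plspm(d2, two_block_spec())
  expect_equal(fit2$gof, sqrt(unname(fit2$r2["Y"])), tolerance = 1e-10)
})

test_that("bootstrap reports are deterministic and calibrated on planted effects", {
  d <- planted_two_block(269, beta = 0.8, seed = 83)
  spec <- two_block_spec()
  b1 <- bootstrap_validate(d, spec, n_boot = 200, seed = 9)
  b2 <- bootstrap_validate(d, spec, n_boot = 200, seed = 9)
  expect_identical(b1$table, b2$table)
  expect_true(b1$table$accurate)
  expect_true(b1$table$ci_lower > 0)
  d0 <- planted_two_block(269, beta = 0, seed = 84)
  b0 <- bootstrap_validate(d0, spec, n_boot = 200, seed = 9)
  expect_false(b0$table$accurate)
})

test_that("architecture comparison favors the generating structure", {
  set.seed(85)
  n <- 250
  a <- rnorm(n)
  b <- 0.6 * a + 0.8 * rnorm(n)
  cc <- 0.55 * b + 0.2 * rnorm(n)  # noise_sd ~ 0.2 regime
  d <- data.frame(a, b, cc)
  true_spec <- plspm_spec(list(plspm_block("A", "a"), plspm_block("B", "b"),
                               plspm_block("C", "cc")),
                          data.frame(from = c("A", "B"), to = c("B", "C")))
  deleted <- plspm_spec(list(plspm_block("A", "a"), plspm_block("B", "b"),
                             plspm_block("C", "cc")),
                        data.frame(from = "A", to = "C"))
  cmp <- compare_architectures(d, list(true = true_spec, del = deleted),
                               seed = 2)
  expect_identical(cmp$architecture[1], "true")
  # identical candidates score identically
  cmp2 <- compare_architectures(d, list(s1 = true_spec, s2 = true_spec),
                                seed = 3)
  expect_equal(cmp2$response_r2[1], cmp2$response_r2[2], tolerance = 1e-12)
  expect_equal(cmp2$cv_rmse[1], cmp2$cv_rmse[2], tolerance = 1e-12)
})

test_that("degenerate fits fail loudly", {
  set.seed(86)
  d <- data.frame(x = rnorm(30), y = rnorm(30))
  d$x2 <- d$x  # perfectly collinear predecessors
  spec <- plspm_spec(list(plspm_block("A", "x"), plspm_block("B", "x2"),
                          plspm_block("Y", "y")),
                     data.frame(from = c("A", "B"), to = c("Y", "Y")))
  expect_error(fit_plspm(d, spec), "collinear")
  expect_error(fit_plspm(d[1:5, ], two_block_spec()), "10 complete rows")
  expect_error(fit_plspm(data.frame(x = rnorm(20)), two_block_spec()),
               "absent")
})
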