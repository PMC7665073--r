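test_that("scale_variables standardizes with supplied parameters", {
  panel <- data.frame(x = c(10, 20, 30), price = 1)
  p_id <- scaling_params(c(x = 0), c(x = 1))
  expect_equal(scale_variables(panel, p_id)$x, c(10, 20, 30))
  p <- scaling_params(c(x = 20), c(x = 10))
  expect_equal(scale_variables(panel, p)$x, c(-1, 0, 1))
  expect_equal(scale_variables(data.frame(x = 20), p)$x, 0)
  expect_error(scale_variables(panel, p, vars = c("x", "y")),
               "no scaling parameters")
  expect_error(scaling_params(c(x = 1), c(x = 0)), "> 0")
})

test_that("freight adjustment is additive over modal and ocean legs", {
  sp0 <- freight_spec(c(rail = 1), rates = c(rail = 0), distances = c(rail = 500))
  expect_equal(freight_adjust(600, sp0), 600)
  sp1 <- freight_spec(c(truck = 1), rates = c(truck = 0.05),
                      distances = c(truck = 1000))
  expect_equal(freight_adjust(600, sp1), 650)
  # two modes with equal rate*distance cost the same as one
  sp2 <- freight_spec(c(rail = 0.5, barge = 0.5),
                      rates = c(rail = 0.04, barge = 0.02),
                      distances = c(rail = 1000, barge = 2000))
  expect_equal(freight_adjust(600, sp2), 600 + 40)
  sp3 <- freight_spec(c(rail = 1), rates = c(rail = 0.04),
                      distances = c(rail = 1000),
                      ocean_rate = 0.001, ocean_distance_km = 10000)
  expect_equal(freight_adjust(600, sp3), 600 + 40 + 10)
  expect_error(freight_spec(c(rail = 0.6, truck = 0.3),
                            rates = c(rail = 1, truck = 1),
                            distances = c(rail = 1, truck = 1)), "sum to 1")
})

test_that("freight adjustment is monotone in every rate and distance", {
  base <- freight_spec(c(rail = 0.7, truck = 0.3),
                       rates = c(rail = 0.03, truck = 0.08),
                       distances = c(rail = 1500, truck = 300))
  more <- freight_spec(c(rail = 0.7, truck = 0.3),
                       rates = c(rail = 0.04, truck = 0.08),
                       distances = c(rail = 1500, truck = 400))
  expect_gt(freight_adjust(600, more), freight_adjust(600, base))
})

test_that("zero-noise meal panels are recovered exactly", {
  cfg <- panel_sim_config("meal", random_sd = c(0, 0, 0, 0), resid_sd = 0,
                          seed = 42)
  sim <- simulate_panel(cfg)
  fit <- fit_hedonic_meal(sim$panel, scaling = sim$truth$scaling)
  truth <- sim$truth$beta[names(fit$beta)]
  expect_lt(max(abs(fit$beta - truth) / abs(truth)), 1e-6)
  expect_lt(fit$sigma_resid / mean(sim$panel$price), 1e-8)
})

test_that("zero-noise oil panels are recovered exactly", {
  cfg <- panel_sim_config("oil", random_sd = c(0, 0, 0, 0), resid_sd = 0,
                          seed = 5)
  sim <- simulate_panel(cfg)
  fit <- fit_hedonic_oil(sim$panel, scaling = sim$truth$scaling)
  truth <- sim$truth$beta[names(fit$beta)]
  expect_lt(max(abs(fit$beta - truth) / abs(truth)), 1e-6)
})

test_that("identical compositions give a singular-design error", {
  cfg <- panel_sim_config("meal", seed = 9)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  for (v in c("cp", "ee", "met", "lys")) panel[[v]] <- panel[[v]][1]
  expect_error(fit_hedonic_meal(panel, scaling = sim$truth$scaling),
               "singular|zero variance")
})

test_that("single-year panels fall back to a fixed-effects-only fit", {
  cfg <- panel_sim_config("meal", years = 2019, seed = 10)
  sim <- simulate_panel(cfg)
  expect_warning(fit <- fit_hedonic_meal(sim$panel,
                                         scaling = sim$truth$scaling),
                 "single-year")
  expect_identical(fit$engine, "lm")
  expect_true(all(fit$random$intercept == 0))
})

test_that("noisy mixed fits estimate the generating coefficients", {
  cfg <- panel_sim_config("meal", seed = 7)
  sim <- simulate_panel(cfg)
  fit <- suppressWarnings(fit_hedonic_meal(sim$panel,
                                           scaling = sim$truth$scaling))
  expect_identical(fit$engine, "lmer")
  ci <- confint_fixed(fit)
  truth <- sim$truth$beta[rownames(ci)]
  # a single realization: all five 95% intervals should not all miss
  expect_gt(mean(truth >= ci[, "lower"] & truth <= ci[, "upper"]), 0.5)
  expect_gt(fit$sigma_resid, 0)
  expect_true(is.finite(fit$loglik))
})

test_that("prediction interpolates training commodities at zero noise", {
  cfg <- panel_sim_config("oil", random_sd = c(0, 0, 0, 0), resid_sd = 0,
                          seed = 11)
  sim <- simulate_panel(cfg)
  fit <- fit_hedonic_oil(sim$panel, scaling = sim$truth$scaling)
  row <- sim$panel[4, ]
  pred <- predict_price(fit, row[c("epa", "fa14_0", "fa16_1n7", "fa16_0")],
                        year = row$year)
  expect_equal(pred, row$price, tolerance = 1e-6)
})

test_that("prediction equals a hand-evaluated polynomial in the coefficients", {
  cfg <- panel_sim_config("meal", seed = 13)
  sim <- simulate_panel(cfg)
  fit <- suppressWarnings(fit_hedonic_meal(sim$panel,
                                           scaling = sim$truth$scaling))
  sc <- fit$scaling
  x <- list(cp = 40, ee = 5, met = 1, lys = 3)
  xs <- lapply(names(x), function(v) {
    r <- sc[sc$variable == v, ]
    (x[[v]] - r$center) / r$scale
  })
  names(xs) <- names(x)
  b <- fit$beta
  by_hand <- unname(b["(Intercept)"] + b["I(cp^2)"] * xs$cp^2 +
    b["I(met^2)"] * xs$met^2 + b["I(lys^2)"] * xs$lys^2 + b["ee"] * xs$ee)
  expect_equal(predict_price(fit, x), by_hand, tolerance = 1e-12)

  # composition at the scaling centers: all scaled terms vanish
  x0 <- as.list(setNames(sc$center, sc$variable))
  expect_equal(predict_price(fit, x0), unname(b["(Intercept)"]),
               tolerance = 1e-12)
  # a specific year adds that year's random coefficients
  y1 <- fit$random$year[1]
  re <- fit$random[1, ]
  expect_equal(predict_price(fit, x0, year = y1),
               unname(b["(Intercept)"]) + re$intercept, tolerance = 1e-12)
  each <- predict_price(fit, x0, year = "each")
  expect_equal(length(each), nrow(fit$random))
})

test_that("far-out-of-range compositions trigger an extrapolation warning", {
  cfg <- panel_sim_config("meal", seed = 14)
  sim <- simulate_panel(cfg)
  fit <- suppressWarnings(fit_hedonic_meal(sim$panel,
                                           scaling = sim$truth$scaling))
  expect_warning(predict_price(fit, list(cp = 200, ee = 5, met = 1, lys = 3)),
                 "extrapolation")
})

test_that("prediction is invariant to the scaling choice for linear structure", {
  # prices depend only linearly on ee: both scalings fit the data exactly,
  # so predictions at any probe must agree
  set.seed(21)
  comp <- data.frame(cp = runif(12, 10, 70), ee = runif(12, 1, 12),
                     met = runif(12, 0.2, 2.2), lys = runif(12, 0.5, 5.5))
  panel <- do.call(rbind, lapply(2010:2019, function(y) {
    data.frame(commodity = sprintf("C%02d", 1:12), year = y,
               price = 600 + 35 * comp$ee, comp)
  }))
  s1 <- panel_scaling(panel, c("cp", "ee", "met", "lys"))
  s2 <- scaling_params(
    setNames(rep(0, 4), c("cp", "ee", "met", "lys")),
    setNames(c(10, 2, 0.5, 1), c("cp", "ee", "met", "lys"))
  )
  f1 <- fit_hedonic_meal(panel, scaling = s1)
  f2 <- fit_hedonic_meal(panel, scaling = s2)
  probe <- list(cp = 55, ee = 8, met = 1.5, lys = 2)
  expect_equal(predict_price(f1, probe), predict_price(f2, probe),
               tolerance = 1e-6)
})

test_that("oil price converts to whole-cell price by the lipid fraction", {
  expect_equal(oil_to_whole_cell(1.0, 0.54), 0.54)
  expect_equal(oil_to_whole_cell(3.3, 1.0), 3.3)
  expect_equal(round(oil_to_whole_cell(4.407, 0.54), 2), 2.38)
  expect_error(oil_to_whole_cell(1, 0), "0, 1")
  expect_error(oil_to_whole_cell(1, 1.2), "0, 1")
})
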