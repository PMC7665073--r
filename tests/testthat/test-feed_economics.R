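test_that("feed cost is the inclusion-weighted price sum", {
  expect_equal(feed_cost(c(only = 100), list(only = 2.5)), 2.5)
  expect_equal(feed_cost(c(a = 50, b = 50), list(a = 1.0, b = 3.0)), 2.0)
  expect_error(feed_cost(c(a = 50, b = 50), list(a = 1.0)), "\\bb\\b")
  expect_error(feed_cost(c(a = 10, b = 10), list(a = 1, b = 1)), "sum to")
  # element-wise over bootstrap sample vectors
  fc <- feed_cost(c(a = 50, b = 50), list(a = c(1, 2), b = 3))
  expect_equal(fc, c(2.0, 2.5))
})

test_that("the fish-free diet costs 0.68 USD/kg under the constructed price set", {
  form <- table1_formulation()
  prices <- table6_price_set(form)
  f100 <- form[form$diet == "100NS", ]
  expect_equal(feed_cost(f100, prices), 0.68, tolerance = 1e-9)
  expect_equal(feed_cost(form[form$diet == "Reference", ], prices), 0.64,
               tolerance = 1e-9)
})

test_that("feed cost is monotone nondecreasing in every ingredient price", {
  form <- c(a = 40, b = 35, c = 25)
  p0 <- list(a = 1, b = 2, c = 3)
  base <- feed_cost(form, p0)
  for (ing in names(p0)) {
    p1 <- p0
    p1[[ing]] <- p1[[ing]] + 0.5
    expect_gt(feed_cost(form, p1), base)
  }
})

test_that("ECR is the FCR-price product and matches the published table", {
  expect_equal(ecr(1.40, 0.68), 0.952)
  expect_equal(round(ecr(1.40, 0.68), 2), 0.95)
  expect_equal(round(ecr(1.61, 0.64), 2), 1.03)
  expect_error(ecr(1.4, 0), "positive")
  expect_error(ecr(0, 0.68), "positive")
})

test_that("ECR is bilinear", {
  set.seed(2)
  f <- runif(10, 1, 2); p <- runif(10, 0.4, 1); a <- runif(10, 0.5, 3)
  expect_equal(ecr(a * f, p), a * ecr(f, p))
  expect_equal(ecr(f, a * p), a * ecr(f, p))
})

test_that("bootstrap median CI handles degenerate and small samples", {
  expect_warning(b <- bootstrap_median_ci(c(5, 5, 5, 5), seed = 1),
                 "constant")
  expect_equal(c(b$median, b$ci_low, b$ci_high), c(5, 5, 5))
  expect_warning(b2 <- bootstrap_median_ci(c(1, 2), n_reps = 1000, seed = 3),
                 "unstable")
  expect_true(b2$ci_low <= b2$median && b2$median <= b2$ci_high)
  expect_error(bootstrap_median_ci(c(1, 2, 3), n_reps = 10, seed = 1),
               ">= 1000")
  expect_error(bootstrap_median_ci(c(1, 2, 3), n_reps = 2000), "seed")
})

test_that("bootstrap median CI is reproducible under a fixed seed", {
  set.seed(99)
  x <- rnorm(60)
  r1 <- bootstrap_median_ci(x, n_reps = 2000, seed = 7)
  r2 <- bootstrap_median_ci(x, n_reps = 2000, seed = 7)
  expect_identical(r1, r2)
  r3 <- bootstrap_median_ci(x, n_reps = 2000, seed = 8)
  expect_false(identical(r1$ci_low, r3$ci_low))
  expect_identical(r1$method, "bca")
  expect_true(r1$ci_low <= r1$median && r1$median <= r1$ci_high)
})

test_that("per-ingredient ECR contributions sum exactly to the total", {
  form <- table1_formulation()
  prices <- table6_price_set(form)
  for (d in unique(form$diet)) {
    f_d <- form[form$diet == d, ]
    dis <- ecr_disaggregate(f_d, prices, fcr = 1.5)
    total <- ecr(1.5, feed_cost(f_d, prices))
    expect_equal(sum(dis$contribution_usd_per_kg_fish), total,
                 tolerance = 1e-9)
  }
})

test_that("identical diets give equal medians and one Tukey letter", {
  form <- do.call(rbind, lapply(c("A", "B", "C"), function(d) {
    data.frame(diet = d, ingredient = c("x", "y"), g_per_100g = c(60, 40))
  }))
  prices <- list(x = 0.5, y = 1.0)
  tanks <- make_tanks(list(A = c(1.5, 1.6, 1.4), B = c(1.5, 1.6, 1.4),
                           C = c(1.5, 1.6, 1.4)))
  tab <- ecr_table(form, prices, tanks, n_reps = 2000, seed = 5)
  expect_equal(length(unique(tab$feed_cost_median)), 1)
  expect_equal(length(unique(tab$ecr_median)), 1)
  expect_equal(length(unique(tab$tukey_letter)), 1)
})

test_that("ecr_table reproduces the published cost/FCR/ECR products", {
  form <- table1_formulation()
  prices <- table6_price_set(form)
  fcrs <- list(Reference = c(1.51, 1.61, 1.71), `33NS` = c(1.47, 1.57, 1.67),
               `66NS` = c(1.50, 1.60, 1.70), `100NS` = c(1.30, 1.40, 1.50))
  tanks <- make_tanks(fcrs)
  tab <- ecr_table(form, prices, tanks, n_reps = 4000, seed = 20201112)
  tab <- tab[match(c("Reference", "33NS", "66NS", "100NS"), tab$diet), ]
  expect_equal(tab$feed_cost_median, c(0.64, 0.72, 0.70, 0.68),
               tolerance = 1e-9)
  expect_equal(tab$fcr_mean, c(1.61, 1.57, 1.60, 1.40), tolerance = 1e-9)
  # ECR medians near the published FCR x cost products
  expect_equal(tab$ecr_median, c(1.03, 1.13, 1.12, 0.95), tolerance = 0.05)
  expect_true(all(tab$ecr_lo <= tab$ecr_median &
                    tab$ecr_median <= tab$ecr_hi))
  expect_false(is.null(attr(tab, "anova")))
})

test_that("ecr_table validates coverage of diets and prices", {
  form <- data.frame(diet = "A", ingredient = c("x", "y"),
                     g_per_100g = c(60, 40))
  tanks <- make_tanks(list(A = c(1.5, 1.6)))
  expect_error(ecr_table(form, list(x = 0.5), tanks, n_reps = 1000, seed = 1),
               "\\by\\b")
  expect_error(
    ecr_table(rbind(form, data.frame(diet = "B", ingredient = "x",
                                     g_per_100g = 100)),
              list(x = 0.5, y = 1), tanks, n_reps = 1000, seed = 1),
    "no tank records")
})
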