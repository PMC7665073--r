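# Feed cost per kg from diet formulations, economic conversion ratio
# (ECR = FCR x feed price), and bootstrap uncertainty.

#' Cost of a formulated feed
#'
#' `sum(inclusion/100 * price_per_kg)` over all ingredients of one diet.
#' When ingredient prices are supplied as bootstrap sample vectors the sum is
#' applied element-wise, yielding a feed-cost distribution.
#'
#' @param formulation Either a named numeric vector (ingredient -> g per
#'   100 g diet) or a data frame with columns `ingredient`, `g_per_100g`
#'   (one diet).
#' @param prices Named list or vector: ingredient -> price (USD/kg), each a
#'   scalar or a sample vector (equal lengths across vector-valued entries).
#' @param tol_total Allowed deviation of total inclusion from 100 g (default
#'   1.0 g).
#' @return Feed cost in USD/kg feed: a scalar, or a vector if any price was
#'   a sample vector.
#' @export
feed_cost <- function(formulation, prices, tol_total = 1.0) {
  if (is.data.frame(formulation)) {
    inc <- stats::setNames(formulation$g_per_100g,
                           as.character(formulation$ingredient))
  } else {
    inc <- formulation
  }
  if (is.null(names(inc)) || anyNA(inc) || any(inc < 0)) {
    stop_invalid("formulation must be named, non-missing and non-negative")
  }
  if (abs(sum(inc) - 100) > tol_total) {
    stop_invalid("inclusions sum to ", round(sum(inc), 3),
                 " g/100 g (must be 100 within ", tol_total, ")")
  }
  inc <- inc[inc > 0]
  unpriced <- setdiff(names(inc), names(prices))
  if (length(unpriced)) {
    stop_invalid("no price for ingredient(s): ",
                 paste(unpriced, collapse = ", "))
  }
  lens <- vapply(prices[names(inc)], length, integer(1))
  n_out <- max(lens)
  if (!all(lens %in% c(1L, n_out))) {
    stop_invalid("price sample vectors must share a common length")
  }
  cost <- numeric(n_out)
  for (ing in names(inc)) {
    p <- prices[[ing]]
    if (any(p <= 0)) stop_invalid("non-positive price for ", ing)
    cost <- cost + inc[[ing]] / 100 * p
  }
  unname(cost)
}

#' Economic conversion ratio
#'
#' `ECR = FCR x price of diet`: the feed cost (USD) per kg of fish weight
#' gain. Bilinear in both arguments; vectorised.
#'
#' @param fcr Feed conversion ratio (> 0).
#' @param diet_price Feed price, USD/kg feed (> 0).
#' @return ECR in USD per kg fish.
#' @examples
#' ecr(1.40, 0.68) # 0.952 USD/kg tilapia
#' @export
ecr <- function(fcr, diet_price) {
  check_positive(fcr, "fcr")
  check_positive(diet_price, "diet_price")
  fcr * diet_price
}

#' BCa bootstrap confidence interval for the median
#'
#' Nonparametric bootstrap of the sample median with a bias-corrected and
#' accelerated ("adjusted percentile") 95% interval, computed by
#' [boot::boot()] and [boot::boot.ci()]. Bit-reproducible for a fixed seed.
#'
#' A constant sample collapses the interval to the point (with a warning);
#' a two-point sample runs but warns that the BCa acceleration estimate is
#' unstable. If the BCa endpoints are undefined (degenerate jackknife), the
#' percentile interval is returned with a warning.
#'
#' @param sample Numeric vector, length >= 2.
#' @param n_reps Bootstrap replicates (default 10000, minimum 1000).
#' @param seed Integer seed (required).
#' @param conf Confidence level (default 0.95).
#' @return List: `median`, `ci_low`, `ci_high`, `n_reps`, `seed`, `method`.
#' @export
bootstrap_median_ci <- function(sample, n_reps = 10000, seed, conf = 0.95) {
  if (length(sample) < 2 || anyNA(sample)) {
    stop_invalid("`sample` must have >= 2 non-missing values")
  }
  if (n_reps < 1000) stop_invalid("`n_reps` must be >= 1000")
  seed <- check_scalar_seed(seed)
  med <- stats::median(sample)
  if (stats::sd(sample) == 0) {
    warning("constant sample: confidence interval collapses to the point")
    return(list(median = med, ci_low = med, ci_high = med,
                n_reps = n_reps, seed = seed, method = "degenerate"))
  }
  if (length(sample) == 2) {
    warning("two-point sample: BCa acceleration estimate is unstable")
  }
  withr::local_seed(seed)
  b <- boot::boot(sample, function(d, i) stats::median(d[i]), R = n_reps)
  ci <- tryCatch(
    boot::boot.ci(b, conf = conf, type = "bca"),
    error = function(e) NULL, warning = function(w) {
      tryCatch(suppressWarnings(boot::boot.ci(b, conf = conf, type = "bca")),
               error = function(e) NULL)
    })
  if (!is.null(ci) && !is.null(ci$bca) && all(is.finite(ci$bca[4:5]))) {
    return(list(median = med, ci_low = ci$bca[4], ci_high = ci$bca[5],
                n_reps = n_reps, seed = seed, method = "bca"))
  }
  warning("BCa interval undefined for this sample; ",
          "falling back to the percentile interval")
  ci <- boot::boot.ci(b, conf = conf, type = "perc")
  list(median = med, ci_low = ci$percent[4], ci_high = ci$percent[5],
       n_reps = n_reps, seed = seed, method = "percentile")
}

#' Per-ingredient ECR contributions
#'
#' Disaggregates a diet's ECR by ingredient:
#' `inclusion/100 * price * FCR`. Contributions sum exactly to the total ECR.
#'
#' @inheritParams feed_cost
#' @param fcr Feed conversion ratio of the diet.
#' @return Tibble: `ingredient`, `contribution_usd_per_kg_fish`.
#' @export
ecr_disaggregate <- function(formulation, prices, fcr) {
  check_positive(fcr, "fcr")
  if (is.data.frame(formulation)) {
    inc <- stats::setNames(formulation$g_per_100g,
                           as.character(formulation$ingredient))
  } else {
    inc <- formulation
  }
  inc <- inc[inc > 0]
  unpriced <- setdiff(names(inc), names(prices))
  if (length(unpriced)) {
    stop_invalid("no price for ingredient(s): ",
                 paste(unpriced, collapse = ", "))
  }
  p <- vapply(names(inc), function(ing) prices[[ing]][1], numeric(1))
  tibble::tibble(
    ingredient = names(inc),
    contribution_usd_per_kg_fish = unname(inc / 100 * p * fcr)
  )
}

#' Feed cost, FCR and ECR table with bootstrap uncertainty
#'
#' For each diet: the feed-cost median and 95% interval from a nonparametric
#' bootstrap over ingredient price observations; the FCR mean and SE across
#' tank replicates; and the ECR median and 95% interval from the product of
#' resampled tank FCRs and bootstrapped feed costs. Significance of diet
#' differences in ECR is assessed by one-way ANOVA with Tukey HSD letters on
#' per-tank point ECRs (tank FCR times the diet's median feed cost), the tank
#' being the replicate unit.
#'
#' Each bootstrap replicate resamples, with replacement, every ingredient's
#' annual price observations (taking the replicate's median price) and one
#' tank FCR; scalar prices are carried through unchanged.
#'
#' @param formulations Data frame: `diet`, `ingredient`, `g_per_100g`.
#' @param prices Named list: ingredient -> USD/kg, scalar or a vector of
#'   annual price observations to be bootstrapped.
#' @param tanks Tank records (see [tank_metrics()]) covering every diet with
#'   >= 2 replicate tanks.
#' @param n_reps Bootstrap replicates (default 10000).
#' @param seed Integer seed (required).
#' @param alpha Significance level for the Tukey letters.
#' @return Tibble with one row per diet: `diet`, `feed_cost_median`,
#'   `feed_cost_lo`, `feed_cost_hi`, `fcr_mean`, `fcr_se`, `ecr_median`,
#'   `ecr_lo`, `ecr_hi`, `tukey_letter`; the ANOVA on point ECRs is attached
#'   as attribute `"anova"`.
#' @export
ecr_table <- function(formulations, prices, tanks, n_reps = 10000, seed,
                      alpha = 0.05) {
  seed <- check_scalar_seed(seed)
  required <- c("diet", "ingredient", "g_per_100g")
  missing <- setdiff(required, names(formulations))
  if (length(missing)) {
    stop_invalid("formulations missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  metrics <- tank_metrics(tanks)
  diets <- unique(formulations$diet)
  no_tanks <- setdiff(diets, unique(metrics$diet))
  if (length(no_tanks)) {
    stop_invalid("no tank records for diet(s): ",
                 paste(no_tanks, collapse = ", "))
  }

  withr::local_seed(seed)
  rows <- list()
  ecr_points <- list()
  for (d in diets) {
    f_d <- formulations[formulations$diet == d, , drop = FALSE]
    inc <- stats::setNames(f_d$g_per_100g, as.character(f_d$ingredient))
    tank_fcr <- metrics$fcr[metrics$diet == d]
    if (length(tank_fcr) < 2) {
      stop_invalid("diet ", d, " needs >= 2 replicate tanks")
    }

    used <- names(inc)[inc > 0]
    unpriced <- setdiff(used, names(prices))
    if (length(unpriced)) {
      stop_invalid("no price for ingredient(s): ",
                   paste(unpriced, collapse = ", "))
    }
    # bootstrap replicate price per ingredient: median of a resample of its
    # annual observations (scalars stay fixed)
    boot_prices <- lapply(prices[used], function(p) {
      if (length(p) == 1) rep(p, n_reps)
      else vapply(seq_len(n_reps), function(r) {
        stats::median(base::sample(p, length(p), replace = TRUE))
      }, numeric(1))
    })
    fc_samples <- feed_cost(inc, boot_prices)
    fc_med <- stats::median(fc_samples)
    fc_ci <- stats::quantile(fc_samples, c(0.025, 0.975), names = FALSE)

    fcr_boot <- base::sample(tank_fcr, n_reps, replace = TRUE)
    ecr_samples <- fcr_boot * fc_samples
    ecr_med <- stats::median(ecr_samples)
    ecr_ci <- stats::quantile(ecr_samples, c(0.025, 0.975), names = FALSE)

    ecr_points[[as.character(d)]] <- tank_fcr * fc_med
    rows[[as.character(d)]] <- tibble::tibble(
      diet = d,
      feed_cost_median = fc_med, feed_cost_lo = fc_ci[1],
      feed_cost_hi = fc_ci[2],
      fcr_mean = mean(tank_fcr),
      fcr_se = stats::sd(tank_fcr) / sqrt(length(tank_fcr)),
      ecr_median = ecr_med, ecr_lo = ecr_ci[1], ecr_hi = ecr_ci[2]
    )
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  an <- anova_oneway(ecr_points, alpha = alpha)
  out$tukey_letter <- unname(an$letters[as.character(out$diet)])
  attr(out, "anova") <- an
  out
}
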