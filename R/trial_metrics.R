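#' Absolute weight gain
#'
#' Weight gain in grams over the trial, `w_final - w_initial`. Mean wet
#' weights per fish are used throughout, so gain is a per-fish quantity.
#'
#' @param w_final Final mean wet weight (g), > 0.
#' @param w_initial Initial mean wet weight (g), > 0.
#' @return Weight gain (g). Vectorised over both arguments.
#' @examples
#' weight_gain(139.9, 33.3)
#' @export
weight_gain <- function(w_final, w_initial) {
  check_positive(w_final, "w_final")
  check_positive(w_initial, "w_initial")
  w_final - w_initial
}

#' Percentage weight gain
#'
#' `100 * (w_final - w_initial) / w_initial`.
#'
#' @inheritParams weight_gain
#' @return Weight gain as percent of initial weight.
#' @export
weight_gain_pct <- function(w_final, w_initial) {
  check_positive(w_final, "w_final")
  check_positive(w_initial, "w_initial")
  100 * (w_final - w_initial) / w_initial
}

#' Feed conversion ratio
#'
#' FCR = feed intake / weight gain, both in grams per fish. Lower is more
#' efficient. A non-positive gain leaves FCR undefined and is an error rather
#' than a silent NA: tanks that lost weight must be handled explicitly.
#'
#' @param feed_intake Total feed fed per fish (g), >= 0.
#' @param weight_gain Weight gain per fish (g), > 0.
#' @return Dimensionless FCR.
#' @export
fcr <- function(feed_intake, weight_gain) {
  check_nonnegative(feed_intake, "feed_intake")
  if (!is.numeric(weight_gain) || anyNA(weight_gain) || any(weight_gain <= 0)) {
    stop_invalid("FCR is undefined for non-positive weight gain; ",
                 "inspect negative-growth tanks explicitly")
  }
  feed_intake / weight_gain
}

#' Specific growth rate
#'
#' SGR (%/day) = 100 * (ln w_final - ln w_initial) / days. Depends only on
#' the weight ratio, so it is invariant to a common rescaling of both weights.
#'
#' @inheritParams weight_gain
#' @param days Trial duration in days, > 0.
#' @return SGR in percent body weight per day.
#' @export
sgr <- function(w_final, w_initial, days) {
  check_positive(w_final, "w_final")
  check_positive(w_initial, "w_initial")
  check_positive(days, "days")
  100 * (log(w_final) - log(w_initial)) / days
}

#' Protein efficiency ratio
#'
#' PER = weight gain (g) / protein fed (g).
#'
#' @param weight_gain Weight gain per fish (g).
#' @param protein_fed Total protein fed per fish (g), > 0.
#' @return Dimensionless PER.
#' @export
per <- function(weight_gain, protein_fed) {
  if (!is.numeric(weight_gain) || anyNA(weight_gain)) {
    stop_invalid("`weight_gain` must be numeric and non-missing")
  }
  check_positive(protein_fed, "protein_fed")
  weight_gain / protein_fed
}

#' Survival rate
#'
#' 100 * n_final / n_initial, percent of stocked fish alive at the end of the
#' trial.
#'
#' @param n_final Final fish count, >= 0.
#' @param n_initial Initial fish count, > 0.
#' @return Survival percentage in \[0, 100\] when `n_final <= n_initial`.
#' @export
survival_pct <- function(n_final, n_initial) {
  check_nonnegative(n_final, "n_final")
  check_positive(n_initial, "n_initial")
  100 * n_final / n_initial
}

#' Convert tank-total feed to per-fish feed intake
#'
#' Feed is weighed per tank; per-fish intake divides by the mean of initial
#' and final fish counts, `(n_initial + n_final) / 2`, so that fish lost
#' during the trial contribute for roughly half of it.
#'
#' @param feed_total_g Total feed fed to the tank (g).
#' @param n_initial,n_final Fish counts at stocking and at harvest.
#' @return Feed intake per fish (g).
#' @export
per_fish_feed <- function(feed_total_g, n_initial, n_final) {
  check_nonnegative(feed_total_g, "feed_total_g")
  check_positive(n_initial, "n_initial")
  check_nonnegative(n_final, "n_final")
  feed_total_g / ((n_initial + n_final) / 2)
}

.metric_cols <- c("weight_gain_g", "weight_gain_pct", "fcr", "sgr", "per",
                  "survival_pct")

#' Per-tank growth metrics
#'
#' Computes every growth-performance metric for each tank record. Tanks are
#' the replicate unit: metrics are always computed per tank first and only
#' then averaged across tanks of a diet (see [summarize_diet()]).
#'
#' @param tanks Data frame of tank records with columns `tank_id`, `diet`,
#'   `n_initial`, `n_final`, `w_initial_g`, `w_final_g`, `feed_intake_g`
#'   (per fish), `protein_fed_g` (per fish), `duration_days`.
#' @return A tibble with one row per tank: the identifying columns plus
#'   `weight_gain_g`, `weight_gain_pct`, `fcr`, `sgr`, `per`, `survival_pct`.
#' @export
tank_metrics <- function(tanks) {
  required <- c("tank_id", "diet", "n_initial", "n_final", "w_initial_g",
                "w_final_g", "feed_intake_g", "protein_fed_g", "duration_days")
  missing <- setdiff(required, names(tanks))
  if (length(missing)) {
    stop_invalid("tank records are missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  if (any(tanks$n_final > tanks$n_initial)) {
    stop_invalid("`n_final` exceeds `n_initial` for some tank")
  }
  gain <- weight_gain(tanks$w_final_g, tanks$w_initial_g)
  tibble::tibble(
    tank_id = tanks$tank_id,
    diet = tanks$diet,
    weight_gain_g = gain,
    weight_gain_pct = weight_gain_pct(tanks$w_final_g, tanks$w_initial_g),
    fcr = fcr(tanks$feed_intake_g, gain),
    sgr = sgr(tanks$w_final_g, tanks$w_initial_g, tanks$duration_days),
    per = per(gain, tanks$protein_fed_g),
    survival_pct = survival_pct(tanks$n_final, tanks$n_initial)
  )
}

#' Per-diet mean and standard error of growth metrics
#'
#' Metrics are computed per tank with [tank_metrics()] and then summarised
#' within each diet as mean and standard error (sd / sqrt(n)) across tank
#' replicates. A diet represented by a single tank gets its mean with `se`
#' set to `NA` and a warning, since an SE needs at least two replicates.
#'
#' @inheritParams tank_metrics
#' @return A tibble in long form: `diet`, `metric`, `mean`, `se`, `n`.
#' @export
summarize_diet <- function(tanks) {
  if (is.null(tanks) || nrow(tanks) == 0) {
    stop_invalid("no tank records supplied")
  }
  metrics <- tank_metrics(tanks)
  diets <- unique(metrics$diet)
  singletons <- character()
  rows <- lapply(diets, function(d) {
    sub <- metrics[metrics$diet == d, , drop = FALSE]
    n <- nrow(sub)
    if (n < 2) singletons <<- c(singletons, as.character(d))
    vals <- lapply(.metric_cols, function(m) {
      x <- sub[[m]]
      tibble::tibble(
        diet = d, metric = m, mean = mean(x),
        se = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_,
        n = n
      )
    })
    do.call(rbind, vals)
  })
  if (length(singletons)) {
    warning("standard error unavailable for single-tank diet(s): ",
            paste(singletons, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  tibble::as_tibble(out)
}
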