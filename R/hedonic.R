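# Hedonic mixed-effects pricing of novel feed ingredients from commodity
# price panels: a commodity's price is regressed on its nutrient (meal) or
# fatty-acid (oil) composition with year-level random effects, and the fitted
# surface is evaluated at the novel ingredient's composition.

meal_vars <- c("cp", "ee", "met", "lys")
oil_vars <- c("epa", "fa14_0", "fa16_1n7", "fa16_0")

#' Per-variable scaling parameters
#'
#' @param center Named numeric vector of centering constants.
#' @param scale Named numeric vector of scaling constants (> 0), same names.
#' @return A `scaling_params` object (data frame: variable, center, scale).
#' @export
scaling_params <- function(center, scale) {
  if (!identical(sort(names(center)), sort(names(scale)))) {
    stop_invalid("`center` and `scale` must share the same variable names")
  }
  if (any(scale <= 0)) stop_invalid("all `scale` values must be > 0")
  out <- data.frame(variable = names(center),
                    center = unname(center),
                    scale = unname(scale[names(center)]),
                    stringsAsFactors = FALSE)
  class(out) <- c("scaling_params", class(out))
  out
}

#' Derive standardization parameters from a panel
#'
#' Center = mean, scale = SD of each composition variable across panel rows.
#' Used when externally supplied scaling constants are not available.
#'
#' @param panel Price panel data frame.
#' @param vars Composition variable names.
#' @return A [scaling_params()] object.
#' @export
panel_scaling <- function(panel, vars) {
  missing <- setdiff(vars, names(panel))
  if (length(missing)) {
    stop_invalid("panel missing composition column(s): ",
                 paste(missing, collapse = ", "))
  }
  center <- vapply(panel[vars], mean, numeric(1))
  scale <- vapply(panel[vars], stats::sd, numeric(1))
  if (any(scale == 0)) {
    stop_invalid("zero variance in composition variable(s): ",
                 paste(vars[scale == 0], collapse = ", "))
  }
  scaling_params(center, scale)
}

#' Standardize panel composition variables
#'
#' Replaces each composition variable x by `(x - center) / scale`. Prices are
#' untouched.
#'
#' @param panel Price panel data frame.
#' @param params A [scaling_params()] object covering every variable in `vars`.
#' @param vars Variables to scale; defaults to every variable in `params`
#'   present in the panel.
#' @return The panel with scaled composition columns.
#' @export
scale_variables <- function(panel, params, vars = NULL) {
  if (is.null(vars)) vars <- intersect(params$variable, names(panel))
  missing <- setdiff(vars, params$variable)
  if (length(missing)) {
    stop_invalid("no scaling parameters for: ", paste(missing, collapse = ", "))
  }
  for (v in vars) {
    row <- params[params$variable == v, ]
    panel[[v]] <- (panel[[v]] - row$center) / row$scale
  }
  panel
}

#' Freight specification
#'
#' Domestic multi-modal leg plus an ocean leg to the destination port.
#' Modal shares must sum to 1.
#'
#' @param modal_shares Named numeric vector, transport mode -> share of tonnage.
#' @param rates Named numeric vector, mode -> USD per tonne-km (same modes).
#' @param distances Named numeric vector, mode -> km for the domestic leg.
#' @param ocean_rate USD per tonne-km for the ocean leg (default 0).
#' @param ocean_distance_km Ocean leg distance (default 0).
#' @param destination Port label (metadata only).
#' @return A `freight_spec` list.
#' @export
freight_spec <- function(modal_shares, rates, distances, ocean_rate = 0,
                         ocean_distance_km = 0, destination = "port") {
  if (abs(sum(modal_shares) - 1) > 1e-6) {
    stop_invalid("modal shares must sum to 1 (got ", sum(modal_shares), ")")
  }
  modes <- names(modal_shares)
  if (!all(modes %in% names(rates)) || !all(modes %in% names(distances))) {
    stop_invalid("`rates` and `distances` must cover every mode in ",
                 "`modal_shares`")
  }
  check_nonnegative(rates, "rates")
  check_nonnegative(distances, "distances")
  check_nonnegative(ocean_rate, "ocean_rate")
  check_nonnegative(ocean_distance_km, "ocean_distance_km")
  structure(list(modal_shares = modal_shares, rates = rates[modes],
                 distances = distances[modes], ocean_rate = ocean_rate,
                 ocean_distance_km = ocean_distance_km,
                 destination = destination),
            class = "freight_spec")
}

#' Add freight costs to a free-on-board price
#'
#' `price + sum_mode share * rate * distance + ocean_rate * ocean_distance`,
#' the delivered cost at the destination port. Additive and monotone in every
#' rate and distance.
#'
#' @param price Price (USD/tonne), vectorised.
#' @param spec A [freight_spec()].
#' @return Freight-adjusted price (USD/tonne).
#' @export
freight_adjust <- function(price, spec) {
  if (!inherits(spec, "freight_spec")) {
    stop_invalid("`spec` must be a freight_spec object")
  }
  domestic <- sum(spec$modal_shares * spec$rates * spec$distances)
  price + domestic + spec$ocean_rate * spec$ocean_distance_km
}

# Shared fitting engine. `quad` enter as squared scaled terms, `lin` as
# linear scaled terms, `re` get year-level random slopes (plus one year
# random intercept).
.fit_hedonic <- function(panel, model, quad, lin, re, scaling, reml, re_cov) {
  vars <- union(union(quad, lin), re)
  required <- c("commodity", "year", "price", vars)
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    stop_invalid("panel missing column(s): ", paste(missing, collapse = ", "))
  }
  if (length(unique(panel$commodity)) < 2) {
    stop_invalid("panel needs >= 2 commodities")
  }
  if (is.null(scaling)) scaling <- panel_scaling(panel, vars)
  scaled <- scale_variables(panel, scaling, vars)

  fixed_terms <- c(paste0("I(", quad, "^2)"), lin)
  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", fixed_rhs)), data = scaled)
  if (qr(mm)$rank < ncol(mm)) {
    stop_invalid("singular fixed-effects design: composition vectors do not ",
                 "span the model space (are all commodities identical?)")
  }

  ols <- stats::lm(stats::as.formula(paste("price ~", fixed_rhs)),
                   data = scaled)
  n_years <- length(unique(scaled$year))
  years <- sort(unique(scaled$year))
  re_names <- c("intercept", re)

  zero_ranef <- function() {
    out <- as.data.frame(matrix(0, n_years, length(re_names)))
    names(out) <- re_names
    cbind(year = years, out)
  }

  rel_sigma <- stats::sigma(ols) / max(mean(abs(scaled$price)), 1e-12)
  engine <- "lmer"
  if (n_years < 2) {
    warning("single-year panel: random effects are unidentifiable, ",
            "falling back to a fixed-effects-only fit")
    engine <- "lm"
  } else if (rel_sigma < 1e-8) {
    # data lie exactly on the fixed-effects surface; variance components are
    # degenerate and the OLS solution is the ML solution
    engine <- "lm"
  }

  if (engine == "lm") {
    fit <- ols
    beta <- stats::coef(ols)
    ranef_tab <- zero_ranef()
    sigma_resid <- stats::sigma(ols)
    ll <- as.numeric(stats::logLik(ols))
  } else {
    re_rhs <- if (re_cov == "diagonal") {
      paste0("(1 + ", paste(re, collapse = " + "), " || year)")
    } else {
      paste0("(1 + ", paste(re, collapse = " + "), " | year)")
    }
    form <- stats::as.formula(paste("price ~", fixed_rhs, "+", re_rhs))
    fit <- tryCatch(
      lme4::lmer(form, data = scaled, REML = reml,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore",
                   check.conv.grad = lme4::.makeCC("warning", tol = 5e-3))),
      error = function(e) {
        stop("hedonic mixed-model fit failed to converge: ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (lme4::isSingular(fit)) {
      warning("singular random-effects covariance: one or more variance ",
              "components estimated at zero")
    }
    beta <- lme4::fixef(fit)
    rf <- lme4::ranef(fit)$year
    # with `||` lme4 may split the grouping into several terms; ranef()
    # returns a single data frame per grouping factor either way
    ranef_tab <- zero_ranef()
    if (!is.null(rf)) {
      rn <- as.numeric(rownames(rf))
      if ("(Intercept)" %in% names(rf)) {
        ranef_tab$intercept[match(rn, ranef_tab$year)] <- rf[["(Intercept)"]]
      }
      for (v in re) {
        if (v %in% names(rf)) {
          ranef_tab[[v]][match(rn, ranef_tab$year)] <- rf[[v]]
        }
      }
    }
    sigma_resid <- stats::sigma(fit)
    ll <- as.numeric(stats::logLik(fit))
  }

  ranges <- lapply(scaled[vars], range)
  structure(list(model = model, beta = beta, random = ranef_tab,
                 sigma_resid = sigma_resid, loglik = ll, scaling = scaling,
                 quad = quad, lin = lin, re = re, vars = vars,
                 scaled_ranges = ranges, engine = engine, fit = fit),
            class = "hedonic_fit")
}

#' Fit the meal-ingredient hedonic model
#'
#' Mixed-effects regression of freight-adjusted meal prices (USD/tonne) on
#' standardized composition: fixed effects for the intercept, squared crude
#' protein, squared methionine, squared lysine and linear ether extract;
#' year-level random effects comprising a random intercept and random slopes
#' on crude protein and ether extract. Fitted by maximum likelihood
#' (`reml = FALSE`), matching the convention for comparing fixed-effect
#' structures; REML is available behind the flag.
#'
#' The two covariate-tagged random intercept components of the model
#' specification enter the likelihood only through their sum, so they are
#' estimated as a single year intercept whose variance is the sum of the
#' component variances.
#'
#' @param panel Data frame with columns `commodity`, `year`, `price`
#'   (USD/tonne) and composition columns `cp`, `ee`, `met`, `lys`
#'   (percent of mass), constant per commodity across years.
#' @param scaling Optional [scaling_params()]; defaults to the panel's
#'   mean/SD standardization via [panel_scaling()].
#' @param reml Use REML instead of ML (default FALSE).
#' @param re_cov Random-effects covariance structure: `"diagonal"`
#'   (independent variance components, the default, identifiable with ~10
#'   year levels) or `"free"`.
#' @return A `hedonic_fit` object: fixed effects `beta`, per-year `random`
#'   coefficients, `sigma_resid`, `loglik`, the `scaling` used, scaled
#'   variable ranges, and the underlying fitted model.
#' @export
fit_hedonic_meal <- function(panel, scaling = NULL, reml = FALSE,
                             re_cov = c("diagonal", "free")) {
  re_cov <- match.arg(re_cov)
  .fit_hedonic(panel, model = "meal", quad = c("cp", "met", "lys"),
               lin = "ee", re = c("cp", "ee"), scaling = scaling,
               reml = reml, re_cov = re_cov)
}

#' Fit the oil-ingredient hedonic model
#'
#' As [fit_hedonic_meal()], with the oil structure: fixed effects for the
#' intercept, squared EPA (20:5n-3), squared myristic acid (14:0), squared
#' palmitoleic acid (16:1n-7), and linear 14:0 and 16:0 (palmitic acid);
#' year-level random intercept and random slopes on 14:0 and 16:0.
#'
#' @param panel Data frame with columns `commodity`, `year`, `price`
#'   (USD/tonne) and fatty-acid columns `epa`, `fa14_0`, `fa16_1n7`,
#'   `fa16_0` (percent of total fatty acids).
#' @inheritParams fit_hedonic_meal
#' @return A `hedonic_fit` object.
#' @export
fit_hedonic_oil <- function(panel, scaling = NULL, reml = FALSE,
                            re_cov = c("diagonal", "free")) {
  re_cov <- match.arg(re_cov)
  .fit_hedonic(panel, model = "oil", quad = c("epa", "fa14_0", "fa16_1n7"),
               lin = c("fa14_0", "fa16_0"), re = c("fa14_0", "fa16_0"),
               scaling = scaling, reml = reml, re_cov = re_cov)
}

# straight-line evaluation of the regression surface at scaled covariates
.hedonic_eval <- function(fit, xs, re_row = NULL) {
  beta <- fit$beta
  val <- unname(beta["(Intercept)"])
  for (v in fit$quad) val <- val + unname(beta[paste0("I(", v, "^2)")]) * xs[[v]]^2
  for (v in fit$lin) val <- val + unname(beta[v]) * xs[[v]]
  if (!is.null(re_row)) {
    val <- val + re_row$intercept
    for (v in fit$re) val <- val + re_row[[v]] * xs[[v]]
  }
  val
}

#' Predict a price from a hedonic fit
#'
#' Evaluates the fitted regression surface at a (raw-unit) composition
#' vector, scaled with the fit's scaling parameters. `year = "marginal"`
#' sets year random effects to zero (the population-level price);
#' `year = "each"` returns the per-year price distribution; a specific year
#' adds that year's random coefficients.
#'
#' Predicting outside the training panel's composition range is permitted —
#' pricing a novel ingredient is the point — but a warning flags any scaled
#' variable more than 25% of the observed span beyond the panel's range.
#'
#' @param fit A `hedonic_fit`.
#' @param x Named list/vector of the ingredient's composition in raw units
#'   (meal: `cp`, `ee`, `met`, `lys`; oil: `epa`, `fa14_0`, `fa16_1n7`,
#'   `fa16_0`).
#' @param year `"marginal"` (default), `"each"`, or a year present in the fit.
#' @return Predicted price (USD/tonne); a named vector over years for
#'   `year = "each"`.
#' @export
predict_price <- function(fit, x, year = "marginal") {
  if (!inherits(fit, "hedonic_fit")) stop_invalid("`fit` must be a hedonic_fit")
  x <- as.list(x)
  missing <- setdiff(fit$vars, names(x))
  if (length(missing)) {
    stop_invalid("composition vector missing: ", paste(missing, collapse = ", "))
  }
  xs <- list()
  for (v in fit$vars) {
    row <- fit$scaling[fit$scaling$variable == v, ]
    xs[[v]] <- (x[[v]] - row$center) / row$scale
    rng <- fit$scaled_ranges[[v]]
    span <- diff(rng)
    if (span > 0 &&
        (xs[[v]] < rng[1] - 0.25 * span || xs[[v]] > rng[2] + 0.25 * span)) {
      warning(sprintf(
        "extrapolation: scaled `%s` = %.3f outside panel range [%.3f, %.3f] by > 25%% of span",
        v, xs[[v]], rng[1], rng[2]))
    }
  }
  if (identical(year, "marginal")) {
    return(.hedonic_eval(fit, xs))
  }
  if (identical(year, "each")) {
    out <- vapply(seq_len(nrow(fit$random)), function(i) {
      .hedonic_eval(fit, xs, fit$random[i, , drop = FALSE])
    }, numeric(1))
    names(out) <- fit$random$year
    return(out)
  }
  i <- match(year, fit$random$year)
  if (is.na(i)) stop_invalid("year ", year, " not in the fitted panel")
  .hedonic_eval(fit, xs, fit$random[i, , drop = FALSE])
}

#' Confidence intervals for hedonic fixed effects
#'
#' Confidence intervals for the fixed-effect coefficients of a hedonic fit.
#' The default uses Satterthwaite degrees of freedom (via lmerTest), which
#' accounts for the small number of year grouping levels in a 10-year panel;
#' plain Wald z intervals and profile-likelihood intervals are available.
#' Fixed-effects-only fits (single-year or zero-residual panels) use the
#' t-based OLS intervals.
#'
#' @param fit A `hedonic_fit`.
#' @param level Confidence level (default 0.95).
#' @param method `"satterthwaite"` (default), `"wald"`, or `"profile"`.
#' @return Matrix with one row per fixed effect and columns `lower`, `upper`.
#' @export
confint_fixed <- function(fit, level = 0.95,
                          method = c("satterthwaite", "wald", "profile")) {
  method <- match.arg(method)
  if (!inherits(fit, "hedonic_fit")) stop_invalid("`fit` must be a hedonic_fit")
  a <- 1 - level
  if (fit$engine == "lm") {
    ci <- stats::confint(fit$fit, level = level)
  } else if (method == "satterthwaite") {
    lt <- suppressWarnings(lmerTest::as_lmerModLmerTest(fit$fit))
    cs <- stats::coef(summary(lt))
    q <- stats::qt(1 - a / 2, cs[, "df"])
    ci <- cbind(cs[, "Estimate"] - q * cs[, "Std. Error"],
                cs[, "Estimate"] + q * cs[, "Std. Error"])
    rownames(ci) <- rownames(cs)
  } else if (method == "wald") {
    ci <- stats::confint(fit$fit, parm = "beta_", method = "Wald",
                         level = level)
  } else {
    ci <- stats::confint(fit$fit, parm = "beta_", method = "profile",
                         level = level)
  }
  colnames(ci) <- c("lower", "upper")
  ci
}

#' Convert a microalgal oil price to a whole-cell biomass price
#'
#' Values the whole cell at its oil content: `oil_price * lipid_fraction`.
#' The default fraction 0.54 is the lipid fraction of *Schizochytrium* sp.
#'
#' @param oil_price Oil price (USD/kg or USD/tonne; units carry through).
#' @param lipid_fraction Lipid mass fraction of the whole cell, in (0, 1].
#' @return Whole-cell price in the same units as `oil_price`.
#' @export
oil_to_whole_cell <- function(oil_price, lipid_fraction = 0.54) {
  check_positive(oil_price, "oil_price")
  if (!is.numeric(lipid_fraction) || anyNA(lipid_fraction) ||
      any(lipid_fraction <= 0) || any(lipid_fraction > 1)) {
    stop_invalid("`lipid_fraction` must lie in (0, 1]")
  }
  oil_price * lipid_fraction
}

#' @export
print.hedonic_fit <- function(x, ...) {
  cat(sprintf("Hedonic %s model (%s fit)\n", x$model, x$engine))
  cat("Fixed effects (USD/tonne per scaled unit):\n")
  print(round(x$beta, 3))
  cat(sprintf("Residual SD: %.3f  logLik: %.3f\n", x$sigma_resid, x$loglik))
  invisible(x)
}
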