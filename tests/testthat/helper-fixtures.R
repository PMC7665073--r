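# Shared fixtures, all built in code.

# Published growth-table weight-gain row (means, SEs, n = 3 per diet).
table2_weight_gain <- function() {
  data.frame(
    group = c("Reference", "33NS", "66NS", "100NS"),
    mean = c(106.6, 160.6, 135.8, 172.9),
    se = c(13.1, 21.4, 4.6, 8.4),
    n = 3
  )
}

# Four-diet formulation table shipped with the package.
table1_formulation <- function() {
  read_formulation(system.file("extdata", "formulation_table1.csv",
                               package = "algafeed"))
}

# Synthetic ingredient price set (USD/kg): plausible fixed prices for the
# commodity ingredients, with the remaining four prices solved so that the
# four diet costs equal the published 0.64/0.72/0.70/0.68 USD/kg.
table6_price_set <- function(form = table1_formulation()) {
  fixed <- c(corn_gluten_meal = 0.55, soybean_meal = 0.40,
             wheat_flour = 0.25, cah2po4 = 0.80, mineral_mix = 1.5,
             vitamin_mix = 3.0, fish_oil = 1.70, lysine_hcl = 1.2,
             dl_methionine = 2.5, choline_chloride = 0.8)
  unknowns <- c("fishmeal", "n_oculata_defatted", "schizochytrium", "cmc")
  diets <- c("Reference", "33NS", "66NS", "100NS")
  target <- c(0.64, 0.72, 0.70, 0.68)
  A <- matrix(0, 4, 4, dimnames = list(diets, unknowns))
  K <- numeric(4)
  for (i in seq_along(diets)) {
    f <- form[form$diet == diets[i], ]
    inc <- stats::setNames(f$g_per_100g, f$ingredient) / 100
    A[i, ] <- inc[unknowns]
    K[i] <- sum(inc[names(fixed)] * fixed)
  }
  solved <- solve(A, target - K)
  as.list(c(fixed, stats::setNames(solved, unknowns)))
}

# Tank records with exactly the requested per-tank FCR values.
make_tanks <- function(diet_fcrs, w0 = 34.5, wf = 150, days = 184,
                       n0 = 40, protein_frac = 0.37) {
  rows <- list()
  for (d in names(diet_fcrs)) {
    for (i in seq_along(diet_fcrs[[d]])) {
      gain <- wf - w0
      feed <- diet_fcrs[[d]][i] * gain
      rows[[length(rows) + 1]] <- data.frame(
        tank_id = sprintf("%s_T%d", d, i), diet = d,
        n_initial = n0, n_final = n0,
        w_initial_g = w0, w_final_g = wf,
        feed_intake_g = feed, protein_fed_g = feed * protein_frac,
        duration_days = days
      )
    }
  }
  do.call(rbind, rows)
}
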