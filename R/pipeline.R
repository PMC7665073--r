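# Umbrella pipeline: reads configured inputs, runs every analysis stage that
# has inputs, and writes a reproducible report bundle.

#' Run the full analysis pipeline
#'
#' Composes the analysis stages end to end: growth summary and per-metric
#' ANOVA from tank records; digestibility table from titration records;
#' feed-cost/FCR/ECR table with bootstrap intervals and per-ingredient ECR
#' disaggregation when formulations and ingredient prices are supplied.
#' Stages whose inputs are absent are skipped with a message. Outputs are
#' written as CSV plus a JSON report and a manifest recording the seed,
#' package version and a hash of the effective configuration; a re-run with
#' an identical configuration produces a byte-identical report.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `tanks` (path, required), `titration` (path, optional),
#'   `formulation` (path, optional), `ingredient_prices` (named list
#'   ingredient -> USD/kg scalar or sample vector, or path to a CSV with
#'   columns `ingredient`, `usd_per_kg`), `out_dir` (required), `seed`
#'   (required), `n_reps` (default 10000), `alpha` (default 0.05),
#'   `dh_phase` (default "intestine").
#' @return Invisibly, a list with the computed tables (`growth`, `anova`,
#'   `digestibility`, `ecr`, `ecr_disaggregation`) and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$tanks)) stop_invalid("config must name a `tanks` CSV")
  if (is.null(config$out_dir)) stop_invalid("config must name an `out_dir`")
  seed <- check_scalar_seed(config$seed)
  n_reps <- if (is.null(config$n_reps)) 10000 else config$n_reps
  if (n_reps < 1000) stop_invalid("`n_reps` must be >= 1000")
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  if (alpha <= 0 || alpha >= 0.5) stop_invalid("`alpha` must lie in (0, 0.5)")
  dh_phase <- if (is.null(config$dh_phase)) "intestine" else config$dh_phase
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  results <- list()

  tanks <- run_stage("read_tanks", read_tanks(config$tanks))
  results$growth <- run_stage("trial_metrics", summarize_diet(tanks))
  metrics <- tank_metrics(tanks)
  anova_rows <- lapply(.metric_cols, function(m) {
    vals <- split(metrics[[m]], metrics$diet)
    a <- run_stage(paste0("anova_", m),
                   suppressWarnings(anova_oneway(vals, alpha = alpha)))
    tibble::tibble(metric = m, f_value = a$f_value, p_value = a$p_value,
                   letters = paste(names(a$letters), a$letters,
                                   sep = ":", collapse = ";"))
  })
  results$anova <- tibble::as_tibble(do.call(rbind, anova_rows))

  if (!is.null(config$titration)) {
    titr <- run_stage("read_titration", read_titration(config$titration))
    results$digestibility <- run_stage(
      "digestibility", digestibility_table(titr, reported = dh_phase))
  } else {
    message("no titration input: digestibility stage skipped")
  }

  if (!is.null(config$formulation) && !is.null(config$ingredient_prices)) {
    form <- run_stage("read_formulation", read_formulation(config$formulation))
    prices <- config$ingredient_prices
    if (is.character(prices) && length(prices) == 1) {
      ptab <- run_stage("read_prices", read_table(
        prices, c(ingredient = "character", usd_per_kg = "numeric")))
      prices <- split(ptab$usd_per_kg, ptab$ingredient)
    }
    results$ecr <- run_stage("ecr_table", ecr_table(
      form, prices, tanks, n_reps = n_reps, seed = seed, alpha = alpha))
    disagg <- lapply(unique(form$diet), function(d) {
      f_d <- form[form$diet == d, , drop = FALSE]
      fcr_pt <- mean(metrics$fcr[metrics$diet == d])
      med_prices <- lapply(prices, stats::median)
      cbind(diet = d, ecr_disaggregate(f_d, med_prices, fcr_pt))
    })
    results$ecr_disaggregation <- tibble::as_tibble(do.call(rbind, disagg))
  } else {
    message("no formulation/price inputs: economics stage skipped")
  }

  # write bundle
  for (nm in names(results)) {
    df <- results[[nm]]
    att <- attr(df, "anova")
    if (!is.null(att)) attr(df, "anova") <- NULL
    utils::write.csv(df, file.path(config$out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  report <- lapply(results, function(df) {
    attr(df, "anova") <- NULL
    df
  })
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       dataframe = "rows", digits = NA, pretty = TRUE)

  manifest <- list(
    package = "algafeed",
    version = as.character(utils::packageVersion("algafeed")),
    seed = seed, n_reps = n_reps, alpha = alpha, dh_phase = dh_phase,
    config_hash = config_hash(config),
    inputs = config[intersect(names(config),
                              c("tanks", "titration", "formulation"))]
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Hash a pipeline configuration
#'
#' Canonicalises the configuration to sorted-key JSON and returns its MD5
#' digest; the hash changes iff any configuration value changes.
#'
#' @param config Configuration list.
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  config <- config[order(names(config))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
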