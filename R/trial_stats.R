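# One-way ANOVA with Tukey HSD letters, on raw tank replicates or
# reconstructed from published mean/SE/n summary rows.

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Classical pooled-variance one-way fixed-effects ANOVA over diet groups,
#' followed by Tukey HSD pairwise comparisons converted to a compact letter
#' display: groups that share no letter differ significantly at `alpha`.
#'
#' The ANOVA and the Tukey adjustment are delegated to [stats::aov()] and
#' [stats::TukeyHSD()]; the letter display uses the insert-and-absorb
#' construction (see [tukey_letters()]).
#'
#' @param values Named list: one numeric vector of replicate values per group.
#' @param alpha Significance level for the letter display (default 0.05,
#'   matching a 95% confidence level).
#' @return An object of class `algafeed_anova`: a list with `f_value`,
#'   `p_value`, `df_between`, `df_within`, `letters` (named character vector),
#'   `pairwise` (data frame of Tukey-adjusted p-values), `means`, `alpha`.
#' @export
anova_oneway <- function(values, alpha = 0.05) {
  if (!is.list(values) || length(values) < 2 || is.null(names(values))) {
    stop_invalid("`values` must be a named list of >= 2 groups")
  }
  n_i <- vapply(values, length, integer(1))
  if (any(n_i < 2)) {
    stop_invalid("every group needs >= 2 replicates; offending group(s): ",
                 paste(names(values)[n_i < 2], collapse = ", "))
  }
  groups <- names(values)
  means <- vapply(values, mean, numeric(1))
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    group = factor(rep(groups, n_i), levels = groups)
  )

  within_var <- vapply(values, stats::var, numeric(1))
  if (all(within_var == 0)) {
    # degenerate data: no within-group variability at all
    k <- length(groups)
    dfb <- k - 1L
    dfw <- sum(n_i) - k
    if (stats::var(means) == 0) {
      pmat <- matrix(1, k, k, dimnames = list(groups, groups))
      res <- list(f_value = 0, p_value = 1, df_between = dfb, df_within = dfw,
                  letters = tukey_letters(pmat, means, alpha),
                  pairwise = .pmat_to_pairs(pmat), means = means, alpha = alpha)
    } else {
      warning("zero within-group variance with differing means: ",
              "F is infinite (degenerate data)")
      pmat <- 1 - abs(outer(means, means, "!=")) # 0 where means differ
      dimnames(pmat) <- list(groups, groups)
      res <- list(f_value = Inf, p_value = 0, df_between = dfb, df_within = dfw,
                  letters = tukey_letters(pmat, means, alpha),
                  pairwise = .pmat_to_pairs(pmat), means = means, alpha = alpha)
    }
    class(res) <- "algafeed_anova"
    return(res)
  }

  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pmat <- matrix(NA_real_, length(groups), length(groups),
                 dimnames = list(groups, groups))
  diag(pmat) <- 1
  pair_names <- strsplit(rownames(tuk), "-", fixed = TRUE)
  for (i in seq_along(pair_names)) {
    a <- pair_names[[i]][1]; b <- pair_names[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tuk[i, "p adj"]
  }

  res <- list(
    f_value = tab[["F value"]][1],
    p_value = tab[["Pr(>F)"]][1],
    df_between = tab[["Df"]][1],
    df_within = tab[["Df"]][2],
    letters = tukey_letters(pmat, means, alpha),
    pairwise = .pmat_to_pairs(pmat),
    means = means,
    alpha = alpha
  )
  class(res) <- "algafeed_anova"
  res
}

#' Reconstruct a one-way ANOVA from published group summaries
#'
#' Rebuilds the F test and Tukey HSD letters from per-group mean, standard
#' error and replicate count — the form in which feeding-trial tables are
#' published. The within-group variance of group i is recovered as
#' `n_i * se_i^2` (since se = sd/sqrt(n)), pooled over groups for the error
#' mean square; the between-group mean square comes from the reported means.
#' Tukey p-values use the studentized range with the pooled variance.
#'
#' @param groups Data frame with columns `group`, `mean`, `se`, `n`.
#' @inheritParams anova_oneway
#' @return An `algafeed_anova` object (see [anova_oneway()]).
#' @export
anova_from_summaries <- function(groups, alpha = 0.05) {
  required <- c("group", "mean", "se", "n")
  missing <- setdiff(required, names(groups))
  if (length(missing)) {
    stop_invalid("summary table missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  if (any(groups$se < 0)) stop_invalid("standard errors must be >= 0")
  if (any(groups$n < 2)) stop_invalid("every group needs n >= 2")
  if (nrow(groups) < 2) stop_invalid("need >= 2 groups")

  g <- as.character(groups$group)
  m <- groups$mean
  n <- groups$n
  sd2 <- groups$n * groups$se^2          # sd^2 = n * se^2
  names(m) <- g

  n_tot <- sum(n)
  k <- length(g)
  grand <- sum(n * m) / n_tot
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * sd2)
  df_between <- k - 1L
  df_within <- n_tot - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within

  if (ms_within == 0) {
    if (ss_between == 0) {
      f <- 0; p <- 1
      pmat <- matrix(1, k, k, dimnames = list(g, g))
    } else {
      warning("zero pooled within-group variance with differing means: ",
              "F is infinite (degenerate data)")
      f <- Inf; p <- 0
      pmat <- 1 - abs(outer(m, m, "!="))
      dimnames(pmat) <- list(g, g)
    }
  } else {
    f <- ms_between / ms_within
    p <- stats::pf(f, df_between, df_within, lower.tail = FALSE)
    # Tukey-Kramer studentized range statistic per pair
    pmat <- matrix(NA_real_, k, k, dimnames = list(g, g))
    diag(pmat) <- 1
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        se_pair <- sqrt(ms_within / 2 * (1 / n[i] + 1 / n[j]))
        q <- abs(m[i] - m[j]) / se_pair
        pmat[i, j] <- pmat[j, i] <-
          stats::ptukey(q, nmeans = k, df = df_within, lower.tail = FALSE)
      }
    }
  }

  res <- list(f_value = f, p_value = p, df_between = df_between,
              df_within = df_within,
              letters = tukey_letters(pmat, m, alpha),
              pairwise = .pmat_to_pairs(pmat), means = m, alpha = alpha)
  class(res) <- "algafeed_anova"
  res
}

#' Compact letter display from pairwise p-values
#'
#' Insert-and-absorb construction: start from one set holding every group;
#' for each significant pair, split every set containing both members into
#' two copies, one without each member; drop sets that became subsets of
#' others. Letters are assigned in order of descending group mean. Groups
#' sharing no letter differ significantly at `alpha`; groups sharing at least
#' one letter do not.
#'
#' @param pmat Symmetric matrix of (adjusted) pairwise p-values with group
#'   names as dimnames.
#' @param means Named numeric vector of group means (drives letter order).
#' @param alpha Significance level.
#' @return Named character vector: concatenated letters per group.
#' @export
tukey_letters <- function(pmat, means, alpha = 0.05) {
  groups <- rownames(pmat)
  sets <- list(groups)
  idx <- which(upper.tri(pmat) & pmat < alpha, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- groups[idx[r, 1]]; b <- groups[idx[r, 2]]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: keep only maximal sets
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  # order letters by the best (largest-mean) member of each set
  ord <- order(-vapply(sets, function(s) max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    out[sets[[i]]] <- paste0(out[sets[[i]]], letters[i])
  }
  out
}

.pmat_to_pairs <- function(pmat) {
  g <- rownames(pmat)
  idx <- which(upper.tri(pmat), arr.ind = TRUE)
  data.frame(
    group1 = g[idx[, 1]], group2 = g[idx[, 2]],
    p_adj = pmat[idx], row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.algafeed_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_value, x$p_value))
  cat("Tukey HSD letters (alpha =", x$alpha, "):\n")
  print(x$letters)
  invisible(x)
}
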