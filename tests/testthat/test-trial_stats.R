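# brute-force one-way ANOVA oracle from raw group sums of squares
oracle_anova <- function(values) {
  all_x <- unlist(values)
  grand <- mean(all_x)
  ss_b <- sum(vapply(values, function(x) length(x) * (mean(x) - grand)^2,
                     numeric(1)))
  ss_w <- sum(vapply(values, function(x) sum((x - mean(x))^2), numeric(1)))
  df_b <- length(values) - 1
  df_w <- length(all_x) - length(values)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(f = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}

test_that("identical groups give F = 0, p = 1 and one shared letter", {
  vals <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1), d = c(1, 1, 1))
  res <- anova_oneway(vals)
  expect_equal(res$f_value, 0)
  expect_equal(res$p_value, 1)
  expect_equal(length(unique(res$letters)), 1)
})

test_that("clearly separated groups get distinct letters", {
  set.seed(3)
  vals <- list(lo = c(0, 0, 0) + rnorm(3, 0, 1e-3),
               hi = c(10, 10, 10) + rnorm(3, 0, 1e-3))
  res <- anova_oneway(vals)
  expect_lt(res$p_value, 0.05)
  expect_equal(length(intersect(strsplit(res$letters[["lo"]], "")[[1]],
                                strsplit(res$letters[["hi"]], "")[[1]])), 0)
})

test_that("anova_oneway matches the brute-force sums-of-squares oracle", {
  # groups at the published means with common within-group variance 541.1
  d <- sqrt(541.1)
  vals <- lapply(c(106.6, 160.6, 135.8, 172.9), function(m) m + c(-d, 0, d))
  names(vals) <- c("Reference", "33NS", "66NS", "100NS")
  res <- anova_oneway(vals)
  orc <- oracle_anova(vals)
  expect_equal(res$f_value, orc$f, tolerance = 1e-10)
  expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  expect_equal(res$f_value, 4.76, tolerance = 0.01)

  set.seed(12)
  for (rep in 1:5) {
    vals <- lapply(1:4, function(i) rnorm(3 + rep %% 3, mean = i, sd = 2))
    names(vals) <- paste0("g", 1:4)
    res <- anova_oneway(vals)
    orc <- oracle_anova(vals)
    expect_equal(res$f_value, orc$f, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("zero within-group variance with differing means is degenerate", {
  vals <- list(a = c(1, 1, 1), b = c(2, 2, 2))
  expect_warning(res <- anova_oneway(vals), "degenerate")
  expect_equal(res$f_value, Inf)
  expect_equal(res$p_value, 0)
})

test_that("summary reconstruction matches the published growth-table row", {
  res <- anova_from_summaries(table2_weight_gain())
  expect_equal(res$f_value, 4.763, tolerance = 1e-3)
  expect_equal(res$p_value, 0.03445, tolerance = 1e-3)
  expect_equal(res$df_between, 3)
  expect_equal(res$df_within, 8)
  # letter pattern: extremes differ, intermediates straddle
  expect_false(grepl(res$letters[["Reference"]], res$letters[["100NS"]]))
  shared <- function(a, b) {
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  }
  expect_false(shared(res$letters[["Reference"]], res$letters[["100NS"]]))
  expect_true(shared(res$letters[["33NS"]], res$letters[["Reference"]]))
  expect_true(shared(res$letters[["33NS"]], res$letters[["100NS"]]))
})

test_that("identical group means give F = 0 from summaries", {
  gs <- data.frame(group = c("a", "b", "c"), mean = 5, se = c(1, 2, 3), n = 3)
  res <- anova_from_summaries(gs)
  expect_equal(res$f_value, 0)
  expect_equal(res$p_value, 1)
})

test_that("two equal-n groups reduce to the squared pooled-variance t", {
  set.seed(5)
  x <- rnorm(6, 10, 2); y <- rnorm(6, 13, 2)
  gs <- data.frame(group = c("x", "y"), mean = c(mean(x), mean(y)),
                   se = c(sd(x), sd(y)) / sqrt(6), n = 6)
  res <- anova_from_summaries(gs)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("summaries of raw data reproduce the raw-data ANOVA and letters", {
  set.seed(99)
  for (rep in 1:5) {
    vals <- lapply(1:4, function(i) rnorm(3, mean = 2 * i, sd = 2))
    names(vals) <- paste0("g", 1:4)
    raw <- anova_oneway(vals)
    gs <- data.frame(group = names(vals),
                     mean = vapply(vals, mean, numeric(1)),
                     se = vapply(vals, sd, numeric(1)) / sqrt(3), n = 3)
    rec <- anova_from_summaries(gs)
    expect_equal(rec$f_value, raw$f_value, tolerance = 1e-8)
    expect_equal(rec$p_value, raw$p_value, tolerance = 1e-8)
    expect_equal(rec$letters[names(raw$letters)], raw$letters)
    expect_equal(rec$pairwise$p_adj, raw$pairwise$p_adj, tolerance = 1e-8)
  }
})

test_that("F is invariant under affine transformation of all observations", {
  set.seed(17)
  vals <- lapply(1:3, function(i) rnorm(4, mean = i, sd = 1))
  names(vals) <- paste0("g", 1:3)
  f0 <- anova_oneway(vals)$f_value
  shifted <- lapply(vals, function(x) 3.7 * x - 12)
  expect_equal(anova_oneway(shifted)$f_value, f0, tolerance = 1e-10)
})

test_that("letter display separates exactly the significant pairs", {
  set.seed(23)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    vals <- lapply(seq_len(k), function(i) rnorm(3, mean = runif(1, 0, 6)))
    names(vals) <- paste0("g", seq_len(k))
    res <- anova_oneway(vals)
    lset <- lapply(res$letters, function(s) strsplit(s, "")[[1]])
    for (r in seq_len(nrow(res$pairwise))) {
      g1 <- res$pairwise$group1[r]; g2 <- res$pairwise$group2[r]
      share <- length(intersect(lset[[g1]], lset[[g2]])) > 0
      if (res$pairwise$p_adj[r] < res$alpha) {
        expect_false(share, label = sprintf("rep %d: %s-%s separated", rep, g1, g2))
      } else {
        expect_true(share, label = sprintf("rep %d: %s-%s joined", rep, g1, g2))
      }
    }
  }
})

test_that("input validation on groups and summaries", {
  expect_error(anova_oneway(list(a = 1:3)), ">= 2 groups")
  expect_error(anova_oneway(list(a = 1:3, b = 2)), ">= 2 replicates")
  gs <- table2_weight_gain()
  gs$se[1] <- -1
  expect_error(anova_from_summaries(gs), ">= 0")
})
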