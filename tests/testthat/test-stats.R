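test_that("density records follow count / area with non-exclusive labels", {
  set.seed(201)
  labels <- c(rep(list(c("A", "B")), 50), rep(list("A"), 100))
  cells <- make_cells(runif(150, 0, 931), runif(150, 0, 698), labels)
  ds <- tme_dataset(cells, make_rois(), panel = character())
  d <- density_table(ds, c("A", "B", "Z"))
  a <- d[d$phenotype == "A", ]
  expect_equal(a$count, 150)
  expect_equal(a$density, 150 / 0.649838)
  expect_equal(a$proportion, 1)
  b <- d[d$phenotype == "B", ]
  expect_equal(b$count, 50)
  expect_equal(b$proportion, 50 / 150)
  z <- d[d$phenotype == "Z", ]
  expect_equal(z$count, 0)
  expect_equal(z$density, 0)
  expect_equal(z$proportion, 0)
})

test_that("Kruskal-Wallis H matches the hand value and degenerates to 0", {
  res <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(res$statistic, 7.2)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  same <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_wallis(list(a = 1:3)), "two groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric())), "at least 1")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transformations", {
  set.seed(202)
  samples <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  h0 <- kruskal_wallis(samples, posthoc = FALSE)$statistic
  for (f in list(exp, function(x) x^3, function(x) 5 * x - 2)) {
    ht <- kruskal_wallis(lapply(samples, f), posthoc = FALSE)$statistic
    expect_equal(ht, h0)
  }
})

test_that("Dunn z statistics match the hand-ranked oracle", {
  # pooled ranks of 1..9 are the values themselves: mean ranks 2, 5, 8;
  # variance term N(N+1)/12 * (1/3 + 1/3) = 5 with no ties
  tab <- dunn_posthoc(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(tab$z[tab$level_a == "a" & tab$level_b == "b"], -3 / sqrt(5))
  expect_equal(tab$z[tab$level_a == "a" & tab$level_b == "c"], -6 / sqrt(5))
  expect_equal(tab$adjusted_p, pmin(1, tab$p_value * 3))

  # tie-corrected variance, ranked by hand: values 1,2,2,2,4,5 ->
  # ranks 1,3,3,3,5,6; T = (3^3-3)/(12*5) = 0.4;
  # se^2 = (3.5 - 0.4) * (2/3); z = (7/3 - 14/3) / sqrt(31/15)
  tie <- dunn_posthoc(list(a = c(1, 2, 2), b = c(2, 4, 5)))
  expect_equal(tie$z, (7 / 3 - 14 / 3) / sqrt(31 / 15))
  expect_equal(tie$p_value, 2 * pnorm(-abs(tie$z)))

  ident <- dunn_posthoc(list(a = c(3, 3), b = c(3, 3)))
  expect_equal(ident$z, 0)
  expect_equal(ident$adjusted_p, 1)
})

test_that("Bonferroni adjustment never drops below the raw p and is capped", {
  set.seed(203)
  tab <- dunn_posthoc(list(a = rnorm(5), b = rnorm(5), c = rnorm(5),
                           d = rnorm(5)))
  expect_true(all(tab$adjusted_p >= tab$p_value))
  expect_true(all(tab$adjusted_p <= 1))
  # idempotent on already-capped values
  expect_equal(pmin(1, tab$adjusted_p), tab$adjusted_p)
})

test_that("one-way ANOVA F matches an independent sums-of-squares computation", {
  set.seed(204)
  samples <- list(a = rnorm(5, 0), b = rnorm(5, 1), c = rnorm(5, 2))
  res <- one_way_anova_tukey(samples)
  # independent oracle: explicit SS decomposition
  y <- unlist(samples)
  grand <- mean(y)
  ssb <- sum(sapply(samples, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(sapply(samples, function(g) sum((g - mean(g))^2)))
  f_oracle <- (ssb / 2) / (ssw / 12)
  expect_equal(res$statistic, f_oracle)
  expect_equal(res$df, c(2, 12))
  expect_equal(res$details$ss_total, ssb + ssw)
  expect_equal(nrow(res$posthoc), 3)
  expect_true(all(res$posthoc$adjusted_p >= 0 & res$posthoc$adjusted_p <= 1))
})

test_that("one-way ANOVA handles identical and degenerate groups per contract", {
  ident <- one_way_anova_tukey(list(a = 1:3, b = 1:3))
  expect_lt(abs(ident$statistic), 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-12)

  flat_equal <- one_way_anova_tukey(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(flat_equal$statistic, 0)
  expect_equal(flat_equal$p_value, 1)

  flat_diff <- one_way_anova_tukey(list(a = c(1, 1), b = c(2, 2)))
  expect_true(is.infinite(flat_diff$statistic))
  expect_true(isTRUE(flat_diff$details$degenerate))
})

test_that("two-way interaction ANOVA recovers pure-interaction and additive patterns", {
  # additive, zero noise: interaction SS = 0, F = 0
  add <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:2)
  add$value <- ifelse(add$a == "y", 1, 0) + ifelse(add$b == "v", 2, 0)
  res_add <- two_way_interaction_anova(add)
  expect_equal(res_add$details$ss_ab, 0)
  expect_equal(res_add$statistic, 0)

  # cell means {0, 1; 1, 0}: all signal in the interaction
  pure <- expand.grid(a = c("x", "y"), b = c("u", "v"), rep = 1:2)
  pure$value <- as.numeric(xor(pure$a == "y", pure$b == "v"))
  res_pure <- two_way_interaction_anova(pure)
  expect_equal(res_pure$details$ss_a, 0)
  expect_equal(res_pure$details$ss_b, 0)
  expect_equal(res_pure$details$ss_ab, res_pure$details$ss_total)

  unbalanced <- add[-1, ]
  expect_error(two_way_interaction_anova(unbalanced), "balanced")
})

test_that("sums of squares are conserved on random balanced layouts", {
  set.seed(205)
  for (i in 1:10) {
    la <- sample(2:4, 1); lb <- sample(2:4, 1); reps <- sample(2:4, 1)
    d <- expand.grid(a = paste0("a", 1:la), b = paste0("b", 1:lb),
                     rep = 1:reps)
    d$value <- rnorm(nrow(d))
    res <- two_way_interaction_anova(d)
    ss <- res$details
    expect_equal(ss$ss_a + ss$ss_b + ss$ss_ab + ss$ss_resid, ss$ss_total,
                 tolerance = 1e-9)
  }
})

test_that("compare_density splits per-ROI densities by the requested factor", {
  set.seed(206)
  rois <- make_rois(sprintf("r%d", 1:9),
                    region = rep(c("TC", "IM", "N"), each = 3))
  counts <- c(90, 100, 110, 40, 50, 60, 5, 10, 15)
  cells <- dplyr::bind_rows(lapply(1:9, function(i) {
    make_cells(runif(counts[i], 0, 931), runif(counts[i], 0, 698),
               rep(list("P"), counts[i]), roi_id = rois$roi_id[i],
               prefix = paste0("r", i, "c"))
  }))
  ds <- tme_dataset(cells, rois, panel = character())
  d <- density_table(ds, "P")
  res <- compare_density(d, "P", by = "region", test = "kw")
  expect_lt(res$p_value, 0.05)
  expect_equal(res$df, 2)
})
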