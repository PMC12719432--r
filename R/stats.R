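#' @keywords internal
new_comparison <- function(test, statistic, df, p_value, posthoc = NULL,
                           details = list()) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, posthoc = posthoc, details = details),
            class = "tme_comparison")
}

#' @export
print.tme_comparison <- function(x, ...) {
  cat("<tme_comparison>", x$test, "\n")
  df_txt <- paste(x$df, collapse = ", ")
  cat(sprintf("  statistic = %.5g (df = %s), p = %.4g\n",
              x$statistic, df_txt, x$p_value))
  if (!is.null(x$posthoc) && nrow(x$posthoc) > 0) {
    cat("  post-hoc:\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x A `tme_comparison`.
#' @param ... Unused.
#' @return The post-hoc table as a tibble (empty if none).
#' @export
tidy.tme_comparison <- function(x, ...) {
  if (is.null(x$posthoc)) return(tibble())
  as_tibble(x$posthoc)
}

#' One-row summary of a group comparison
#'
#' @param x A `tme_comparison`.
#' @param ... Unused.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`.
#' @export
glance.tme_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic,
         df = paste(x$df, collapse = ","), p_value = x$p_value)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

check_groups <- function(samples, min_size = 1) {
  if (!is.list(samples) || length(samples) < 2) {
    abort("need at least two groups")
  }
  sizes <- lengths(samples)
  if (any(sizes < min_size)) {
    abort(sprintf("every group needs at least %d observation(s)", min_size))
  }
  if (is.null(names(samples))) {
    names(samples) <- paste0("g", seq_along(samples))
  }
  samples
}

groups_to_frame <- function(samples) {
  tibble(value = unlist(samples, use.names = FALSE),
         g = factor(rep(names(samples), lengths(samples)),
                    levels = names(samples)))
}

#' Kruskal-Wallis rank-sum comparison
#'
#' Tie-corrected H on mid-ranks with the chi-square approximation on k - 1
#' degrees of freedom (used at all sample sizes). All values identical gives
#' H = 0, p = 1.
#'
#' @param samples Named list of numeric vectors, one per group (k >= 2, all
#'   non-empty).
#' @param posthoc If `TRUE` (default) attach [dunn_posthoc()] results.
#' @return A `tme_comparison`.
#' @export
kruskal_wallis <- function(samples, posthoc = TRUE) {
  samples <- check_groups(samples, min_size = 1)
  d <- groups_to_frame(samples)
  if (length(unique(d$value)) == 1) {
    res <- new_comparison("Kruskal-Wallis", 0, length(samples) - 1L, 1)
  } else {
    kt <- kruskal.test(d$value, d$g)
    res <- new_comparison("Kruskal-Wallis",
                          unname(kt$statistic), unname(kt$parameter),
                          unname(kt$p.value))
  }
  if (posthoc) res$posthoc <- dunn_posthoc(samples)
  res
}

#' Dunn's post-hoc pairwise comparisons on mean ranks
#'
#' Pairwise z statistics on mean ranks of the pooled data with the
#' tie-corrected variance `(N(N+1)/12 - T) (1/n_i + 1/n_j)`, where
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided normal
#' p-values, Bonferroni-adjusted over all k(k-1)/2 pairs
#' (`p_adj = min(1, p * m)`).
#'
#' @param samples Named list of numeric vectors (k >= 2, all non-empty).
#' @return Tibble: `level_a`, `level_b`, `z`, `p_value`, `adjusted_p`.
#' @export
dunn_posthoc <- function(samples) {
  samples <- check_groups(samples, min_size = 1)
  d <- groups_to_frame(samples)
  N <- nrow(d)
  rk <- rank(d$value)
  mean_rank <- tapply(rk, d$g, mean)
  n <- tapply(rk, d$g, length)
  ties <- table(d$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- names(samples)
  combs <- utils::combn(lv, 2)
  m <- ncol(combs)
  z <- p <- numeric(m)
  for (j in seq_len(m)) {
    a <- combs[1, j]; b <- combs[2, j]
    se2 <- (N * (N + 1) / 12 - tie_term) * (1 / n[[a]] + 1 / n[[b]])
    if (se2 <= 0) {
      z[j] <- 0; p[j] <- 1
    } else {
      z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / sqrt(se2)
      p[j] <- 2 * pnorm(-abs(z[j]))
    }
  }
  tibble(level_a = combs[1, ], level_b = combs[2, ], z = z, p_value = p,
         adjusted_p = pmin(1, p * m))
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' F = MS_between / MS_within with (k - 1, N - k) degrees of freedom;
#' pairwise Tukey honest-significant-difference comparisons with
#' studentized-range p-values. Zero within-group variance with equal means
#' yields F = 0, p = 1; zero within-group variance with unequal means is
#' flagged degenerate (F infinite, p = 0).
#'
#' @param samples Named list of numeric vectors (k >= 2, each of size >= 2).
#' @return A `tme_comparison` with a Tukey post-hoc table (`level_a`,
#'   `level_b`, `diff`, `adjusted_p`) and SS components in `$details`.
#' @export
one_way_anova_tukey <- function(samples) {
  samples <- check_groups(samples, min_size = 2)
  d <- groups_to_frame(samples)
  k <- length(samples); N <- nrow(d)
  grand <- mean(d$value)
  ss_total <- sum((d$value - grand)^2)
  group_means <- tapply(d$value, d$g, mean)
  n <- tapply(d$value, d$g, length)
  ss_between <- sum(n * (group_means - grand)^2)
  ss_within <- ss_total - ss_between
  details <- list(ss_between = ss_between, ss_within = ss_within,
                  ss_total = ss_total)
  if (ss_within <= .Machine$double.eps * max(1, ss_total)) {
    if (ss_between <= .Machine$double.eps * max(1, ss_total)) {
      return(new_comparison("one-way ANOVA", 0, c(k - 1L, N - k), 1,
                            posthoc = tibble(), details = details))
    }
    return(new_comparison("one-way ANOVA", Inf, c(k - 1L, N - k), 0,
                          posthoc = tibble(),
                          details = c(details, degenerate = TRUE)))
  }
  fit <- aov(value ~ g, data = d)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$g
  pairs_ <- strsplit(rownames(tk), "-", fixed = TRUE)
  posthoc <- tibble(level_a = map_chr(pairs_, 1),
                    level_b = map_chr(pairs_, 2),
                    diff = tk[, "diff"],
                    adjusted_p = tk[, "p adj"])
  new_comparison("one-way ANOVA", f, c(k - 1L, N - k), p,
                 posthoc = posthoc, details = details)
}

#' Two-way ANOVA interaction test on a balanced layout
#'
#' Fits `value ~ A * B` on a balanced two-factor design (equal cell counts
#' >= 2; balance makes the sums-of-squares decomposition unambiguous) and
#' reports the interaction term. Unbalanced layouts are rejected rather than
#' silently choosing among Type I/II/III decompositions.
#'
#' @param data Data frame with columns `value`, `a`, `b` (factors or
#'   coercible).
#' @return A `tme_comparison` for the interaction; `$details` carries the
#'   full SS decomposition (`ss_a`, `ss_b`, `ss_ab`, `ss_resid`,
#'   `ss_total`).
#' @export
two_way_interaction_anova <- function(data) {
  stopifnot(all(c("value", "a", "b") %in% names(data)))
  d <- tibble(value = data$value, a = factor(data$a), b = factor(data$b))
  counts <- table(d$a, d$b)
  if (length(unique(as.vector(counts))) != 1 || min(counts) < 2) {
    abort("unsupported design: layout must be balanced with cell counts >= 2")
  }
  fit <- aov(value ~ a * b, data = d)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  dfs <- tab[["Df"]]
  details <- list(ss_a = ss[1], ss_b = ss[2], ss_ab = ss[3], ss_resid = ss[4],
                  ss_total = sum((d$value - mean(d$value))^2))
  f <- tab[["F value"]][3]
  p <- tab[["Pr(>F)"]][3]
  if (ss[4] <= .Machine$double.eps * max(1, details$ss_total)) {
    # zero residual variance: report the interaction SS share directly
    f <- if (ss[3] <= .Machine$double.eps * max(1, details$ss_total)) 0 else Inf
    p <- if (is.infinite(f)) 0 else 1
  }
  new_comparison("two-way interaction ANOVA", f, c(dfs[3], dfs[4]), p,
                 details = details)
}

#' Compare a density-table metric across a grouping factor
#'
#' Convenience wrapper: filters a [density_table()] to one phenotype
#' (optionally one group or one region), splits the chosen metric by the
#' grouping factor and runs the requested test.
#'
#' @param density A `tme_density` tibble.
#' @param phenotype Phenotype label to compare.
#' @param metric `"density"`, `"count"` or `"proportion"`.
#' @param by Grouping factor: `"region"` or `"group"`.
#' @param within Optional filter: a group label when `by = "region"`, a
#'   region label when `by = "group"`.
#' @param test `"kw"` (Kruskal-Wallis + Dunn) or `"anova"` (one-way ANOVA +
#'   Tukey).
#' @return A `tme_comparison`.
#' @export
compare_density <- function(density, phenotype, metric = "density",
                            by = c("region", "group"), within = NULL,
                            test = c("kw", "anova")) {
  by <- match.arg(by)
  test <- match.arg(test)
  d <- density[density$phenotype == phenotype, ]
  if (!is.null(within)) {
    filter_col <- if (by == "region") "group" else "region"
    d <- d[d[[filter_col]] == within, ]
  }
  if (nrow(d) == 0) abort("no density records left after filtering")
  lev <- if (by == "region") intersect(tme_regions, unique(d$region)) else
    intersect(tme_groups, unique(d$group))
  samples <- lapply(lev, function(l) d[[metric]][d[[by]] == l])
  names(samples) <- lev
  if (test == "kw") kruskal_wallis(samples) else one_way_anova_tukey(samples)
}
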