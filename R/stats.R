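# Statistics layer: descriptive summaries, two-sample t tests (raw or
# summary-statistic), one-way ANOVA with Tukey-Kramer multiple comparisons,
# unbalanced Type III factorial ANOVA, weighted marginal means, and the
# two-group sample-size calculation.

.metric_cols <- c("global_platform_mm", "lateral_platform_mm",
                  "global_apex_mm", "lateral_apex_mm",
                  "depth_mm", "angular_deg")

#' Descriptive summary of a sample
#'
#' Mean, sample SD (n - 1 denominator), range and quartiles (linear
#' interpolation between order statistics, `stats::quantile()` type 7).
#'
#' @param x Numeric vector, `n >= 1`.
#' @return A one-row tibble: `n`, `mean`, `sd`, `min`, `q1`, `median`, `q3`,
#'   `max`. `sd` is `NA` for `n = 1`.
#' @export
describe <- function(x) {
  x <- as.numeric(x)
  if (!length(x) || any(!is.finite(x))) {
    abort_config("`x` must be a non-empty finite numeric vector.")
  }
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(x), mean = mean(x),
                 sd = if (length(x) > 1) sd(x) else NA_real_,
                 min = min(x), q1 = q[1], median = q[2], q3 = q[3],
                 max = max(x))
}

#' Grouped deviation summaries
#'
#' Descriptive summaries of each deviation metric, optionally split by a
#' grouping factor — the "mean +/- SD and range" tables of an accuracy study.
#'
#' @param data A deviation tibble (see [measure_deviations()]).
#' @param by Optional name of a factor column to group by.
#' @param metrics Metric columns to summarise (default: the six standard
#'   ones present in `data`).
#' @param depth `"signed"` (default) or `"absolute"`: how to summarise the
#'   depth deviation. Published tables usually report absolute depth while
#'   box plots are signed.
#' @return A tibble with one row per metric (and group), with the
#'   [describe()] columns.
#' @export
summarise_deviations <- function(data, by = NULL,
                                 metrics = intersect(.metric_cols, names(data)),
                                 depth = c("signed", "absolute")) {
  depth <- match.arg(depth)
  if (!length(metrics)) abort_config("No deviation metric columns found.")
  if (!is.null(by) && !by %in% names(data)) {
    abort_config(paste0("Unknown factor '", by, "'. Available: ",
                        paste(setdiff(names(data), c("id", .metric_cols)),
                              collapse = ", "), "."))
  }
  data <- tibble::as_tibble(data)
  if (depth == "absolute" && "depth_mm" %in% metrics) {
    data$depth_mm <- abs(data$depth_mm)
  }
  long <- tidyr::pivot_longer(data[, c(by, metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  grp <- if (is.null(by)) "metric" else c(by, "metric")
  out <- dplyr::reframe(dplyr::group_by(long, dplyr::across(dplyr::all_of(grp))),
                        describe(.data$value))
  dplyr::arrange(out, match(.data$metric, metrics))
}

# Shared core: both t variants from summary statistics.
t_from_summaries <- function(m1, s1, n1, m2, s2, n2,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) abort_config("Each group needs n >= 2.")
  if (s1 < 0 || s2 < 0) abort_config("SDs must be >= 0.")
  diff <- m1 - m2
  if (variant == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- s1^2 / n1; b <- s2^2 / n2
    se <- sqrt(a + b)
    df <- if (se == 0) n1 + n2 - 2 else {
      (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
    }
  }
  if (se == 0) {
    # Zero variance in both groups: equal means are evidence of nothing
    # (p = 1); distinct means are infinitely separated.
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    stat <- diff / se
    p <- 2 * pt(-abs(stat), df)
  }
  tibble::tibble(method = paste0("two-sample t (", variant, ")"),
                 estimate = diff, statistic = stat, df = df, p_value = p,
                 mean1 = m1, mean2 = m2, n1 = n1, n2 = n2)
}

.as_group_summary <- function(x, what) {
  if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    return(list(mean = x$mean, sd = x$sd, n = x$n))
  }
  x <- as.numeric(x)
  if (length(x) < 2) abort_config(paste0(what, " needs n >= 2 raw values."))
  if (any(!is.finite(x))) abort_config(paste0(what, " contains non-finite values."))
  list(mean = mean(x), sd = sd(x), n = length(x))
}

#' Two-sample t test from raw samples or summary statistics
#'
#' Pooled (Student) or Welch two-sided two-sample t test. Each group may be
#' given either as a raw numeric vector or as a `list(mean =, sd =, n =)` of
#' summary statistics — the latter reproduces published results from printed
#' group summaries. Raw and summary modes agree exactly on matching inputs.
#'
#' @param x,y Numeric vectors or `list(mean =, sd =, n =)` summaries.
#' @param variant `"pooled"` (classic Student, `df = n1 + n2 - 2`; default)
#'   or `"welch"` (Satterthwaite df).
#' @return A one-row tibble: `method`, `estimate` (mean difference),
#'   `statistic`, `df`, `p_value`, group means and sizes.
#' @examples
#' two_sample_t(list(mean = 1.24, sd = 0.68, n = 21),
#'              list(mean = 0.92, sd = 0.49, n = 35))
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  gx <- .as_group_summary(x, "`x`")
  gy <- .as_group_summary(y, "`y`")
  t_from_summaries(gx$mean, gx$sd, gx$n, gy$mean, gy$sd, gy$n,
                   match.arg(variant))
}

.split_groups <- function(data, outcome, group) {
  for (col in c(outcome, group)) {
    if (!col %in% names(data)) {
      abort_config(paste0("Unknown column '", col, "'. Available: ",
                          paste(names(data), collapse = ", "), "."))
    }
  }
  split(data[[outcome]], factor(data[[group]]))
}

#' One-way ANOVA
#'
#' Standard between/within decomposition via [stats::aov()].
#'
#' @param data A data frame.
#' @param outcome Name of the numeric outcome column.
#' @param group Name of the grouping column (>= 2 levels, each n >= 2).
#' @return A tibble ANOVA table: `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p_value` (residual row included).
#' @export
one_way_anova <- function(data, outcome, group) {
  gs <- .split_groups(data, outcome, group)
  if (length(gs) < 2) abort_config("One-way ANOVA needs >= 2 groups.")
  if (any(lengths(gs) < 2)) {
    abort_config(paste0("Every group needs n >= 2; too small: ",
                        paste(names(gs)[lengths(gs) < 2], collapse = ", "), "."))
  }
  df <- data.frame(y = as.numeric(data[[outcome]]),
                   g = factor(data[[group]]))
  tab <- summary(aov(y ~ g, data = df))[[1]]
  tibble::tibble(term = c(group, "Residuals"),
                 df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
                 statistic = tab$`F value`, p_value = tab$`Pr(>F)`)
}

#' Tukey-Kramer pairwise comparisons
#'
#' All pairwise group comparisons after a one-way ANOVA, using the
#' studentized-range distribution with the Tukey-Kramer unequal-n standard
#' error `sqrt((MSE / 2) (1/n_i + 1/n_j))`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level for the `significant` flag
#'   (default 0.05).
#' @return A tibble with one row per pair: `group1`, `group2`, `estimate`
#'   (mean difference), `se`, `statistic` (studentized range q), `adj_p`,
#'   `significant`.
#' @export
tukey_kramer <- function(data, outcome, group, alpha = 0.05) {
  gs <- .split_groups(data, outcome, group)
  if (length(gs) < 2) abort_config("Tukey-Kramer needs >= 2 groups.")
  if (any(lengths(gs) < 2)) abort_config("Every group needs n >= 2.")
  k <- length(gs)
  ns <- lengths(gs)
  means <- vapply(gs, mean, numeric(1))
  df_err <- sum(ns) - k
  mse <- sum(vapply(gs, function(v) sum((v - mean(v))^2), numeric(1))) / df_err
  pairs <- utils::combn(k, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    est <- unname(means[i1] - means[i2])
    se <- unname(sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2])))
    q <- if (se == 0) if (est == 0) 0 else Inf else abs(est) / se
    p <- ptukey(q, k, df_err, lower.tail = FALSE)
    tibble::tibble(group1 = names(gs)[i1], group2 = names(gs)[i2],
                   estimate = est, se = se, statistic = q, adj_p = p)
  })
  out$significant <- out$adj_p < alpha
  out
}

#' Unbalanced factorial ANOVA (Type III)
#'
#' Fits a linear model in the given factors (all main effects, and if
#' `include_interactions = TRUE` all two-way interactions and the highest
#' order interaction) with sum-to-zero contrasts, and computes partial
#' (Type III) sums of squares via [car::Anova()] — the convention for
#' unbalanced designs, where each term is tested adjusted for all others.
#' Terms made inestimable by empty design cells are dropped with a warning.
#'
#' @param data A data frame (e.g. a deviation cohort).
#' @param outcome Name of the numeric outcome column.
#' @param factors Character vector of factor column names (each must have
#'   >= 2 observed levels).
#' @param include_interactions Include interaction terms (default `TRUE`).
#' @return An object of class `guidedev_anova` wrapping the `lm` fit; use
#'   [tidy()][generics::tidy] for the per-term table (`term`, `sumsq`, `df`,
#'   `statistic`, `p_value`) and [glance()][generics::glance] for model-level
#'   statistics.
#' @export
factorial_anova <- function(data, outcome, factors,
                            include_interactions = TRUE) {
  if (!outcome %in% names(data)) {
    abort_config(paste0("Unknown outcome '", outcome, "'."))
  }
  df <- data.frame(.y = as.numeric(data[[outcome]]))
  for (f in factors) {
    if (!f %in% names(data)) {
      abort_config(paste0("Unknown factor '", f, "'. Available: ",
                          paste(setdiff(names(data), c("id", .metric_cols)),
                                collapse = ", "), "."))
    }
    fac <- factor(data[[f]])
    if (nlevels(droplevels(fac)) < 2) {
      abort_config(paste0("Factor '", f, "' has fewer than 2 observed levels."))
    }
    df[[f]] <- droplevels(fac)
  }
  rhs <- if (include_interactions) paste(factors, collapse = " * ")
         else paste(factors, collapse = " + ")
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- lm(as.formula(paste(".y ~", rhs)), data = df, contrasts = contr)

  if (anyNA(coef(fit))) {
    # Empty cells make some (usually interaction) terms inestimable: drop
    # every term with aliased coefficients and refit on the rest.
    alias_terms <- unique(attr(fit$terms, "term.labels")[
      fit$assign[is.na(coef(fit))]])
    keep <- setdiff(attr(fit$terms, "term.labels"), alias_terms)
    warning("Dropping inestimable term(s) (empty design cells): ",
            paste(alias_terms, collapse = ", "), call. = FALSE)
    fit <- lm(as.formula(paste(".y ~", paste(keep, collapse = " + "))),
              data = df, contrasts = contr)
  }

  a3 <- car::Anova(fit, type = 3)
  tab <- tibble::tibble(term = rownames(a3), sumsq = a3$`Sum Sq`,
                        df = a3$Df, statistic = a3$`F value`,
                        p_value = a3$`Pr(>F)`)
  tab <- tab[tab$term != "(Intercept)", ]
  structure(list(fit = fit, table = tab, outcome = outcome,
                 factors = factors),
            class = "guidedev_anova")
}

#' @export
print.guidedev_anova <- function(x, ...) {
  cat("<guidedev_anova> Type III factorial ANOVA of", x$outcome, "\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Tidy a factorial ANOVA
#'
#' @param x A `guidedev_anova` object.
#' @param ... Unused.
#' @return `tidy()`: the per-term Type III table; `glance()`: a one-row
#'   tibble with `r.squared`, `df.residual`, `nobs`.
#' @method tidy guidedev_anova
#' @export
tidy.guidedev_anova <- function(x, ...) x$table

#' @rdname tidy.guidedev_anova
#' @method glance guidedev_anova
#' @export
glance.guidedev_anova <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared,
                 df.residual = x$fit$df.residual,
                 nobs = length(x$fit$residuals))
}

#' Count-weighted pooled mean of subgroup means
#'
#' The marginal mean implied by subgroup means and sizes,
#' `sum(n_i m_i) / sum(n_i)` — used to check the arithmetic consistency of
#' published summary tables.
#'
#' @param means Numeric vector of subgroup means.
#' @param ns Subgroup sizes (all >= 1).
#' @return The pooled mean (full precision; round to 2 decimals to compare
#'   with printed tables).
#' @examples
#' round(pooled_mean(c(0.97, 1.84), c(56, 18)), 2)  # 1.18
#' @export
pooled_mean <- function(means, ns) {
  if (!length(means)) abort_config("`means` must be non-empty.")
  if (length(means) != length(ns)) abort_config("`means` and `ns` differ in length.")
  if (any(ns < 1)) abort_config("All subgroup sizes must be >= 1.")
  sum(means * ns) / sum(ns)
}

# Analytic power of the two-sided pooled two-sample t test at a true
# standardized difference delta/sd with groups n1, n2.
t_test_power <- function(delta, sd, n1, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- delta / (sd * sqrt(1 / n1 + 1 / n2))
  crit <- qt(1 - alpha / 2, df)
  pt(-crit, df, ncp) + pt(crit, df, ncp, lower.tail = FALSE)
}

#' Sample size for a two-group t test
#'
#' Smallest per-group n such that the analytic (noncentral-t) power of the
#' two-sided pooled two-sample t test at standardized effect size `d` reaches
#' `power`.
#'
#' @param effect_size_d Cohen's d (> 0).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1) (default 0.05).
#' @return Integer n per group (>= 2).
#' @examples
#' sample_size_two_group_t(1.0, 0.80)  # 17
#' @export
sample_size_two_group_t <- function(effect_size_d, power, alpha = 0.05) {
  if (!is.finite(effect_size_d) || effect_size_d <= 0) {
    abort_config("`effect_size_d` must be > 0.")
  }
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    abort_config("`power` and `alpha` must lie strictly in (0, 1).")
  }
  n <- 2L
  while (t_test_power(effect_size_d, 1, n, n, alpha) < power) {
    n <- n + 1L
    if (n > 1e6) abort_config("Required sample size exceeds 1e6 per group.")
  }
  n
}
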