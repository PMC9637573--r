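#' One-way analysis of variance
#'
#' Classical between/within variance decomposition over temperature
#' groups, as fitted by [stats::aov()]. Requires at least two groups
#' with at least two values each. In the degenerate case of zero
#' within-group variance with equal group means, the F statistic is
#' undefined; by convention p = 1 is returned and flagged.
#'
#' @param data A data frame with columns `value` and `group`.
#' @return One-row tibble: `statistic` (F), `p.value`, `df_between`,
#'   `df_within`, `degenerate`.
#' @export
one_way_anova <- function(data) {
  check_group_data(data)
  g <- split(data$value, data$group)
  scale2 <- mean(data$value^2) + 1e-300
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - mean(data$value))^2,
                     numeric(1)))
  k <- length(g)
  df1 <- k - 1L
  df2 <- length(data$value) - k
  if (ss_w / scale2 < 1e-25 && ss_b / scale2 < 1e-25) {
    warn("Zero within-group variance with equal means; returning p = 1 by convention.")
    return(tibble(statistic = 0, p.value = 1, df_between = df1,
                  df_within = df2, degenerate = TRUE))
  }
  # the perfect-fit warning aov/anova emit for exact data is expected here
  tab <- suppressWarnings(anova(aov(value ~ factor(group), data = data)))
  Fv <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  degenerate <- !is.finite(Fv)
  if (degenerate) {
    warn("Zero within-group variance; returning p = 1 by convention.")
    Fv <- 0; p <- 1
  }
  tibble(statistic = Fv, p.value = p,
         df_between = tab$Df[1], df_within = tab$Df[2],
         degenerate = degenerate)
}

check_group_data <- function(data) {
  if (!all(c("value", "group") %in% names(data))) {
    abort("`data` must have columns `value` and `group`.")
  }
  counts <- table(data$group)
  if (length(counts) < 2) abort("Need at least 2 groups.")
  if (any(counts < 2)) abort("Each group needs at least 2 values.")
  invisible(data)
}

#' Tukey-Kramer multiple comparison
#'
#' All-pairs honest-significant-difference comparison after one-way
#' ANOVA, using the studentized range distribution with Kramer's
#' unequal-sample-size correction: a pair differs at level `alpha` when
#' \deqn{|\bar y_i - \bar y_j| > q_{\alpha,k,\nu}
#'       \sqrt{\tfrac{MSE}{2}\left(\tfrac1{n_i}+\tfrac1{n_j}\right)}.}
#' Per-group comparison intervals are also reported, with halfwidth
#' \eqn{(q/2)\sqrt{(MSE/2)(1/n_i + 1/n_h)}} (harmonic-mean
#' \eqn{n_h}), so that in balanced designs two intervals are disjoint
#' exactly when the pairwise test is significant — the graphical
#' disjoint-interval rule — and the rule is conservative otherwise.
#'
#' @param data A data frame with columns `value` and `group`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `tukey_result`: list with `pairs` (tibble: group pair,
#'   difference, interval, `significant`), `groups` (tibble: mean and
#'   comparison interval per group), `alpha`, `q_crit`, `df`, `mse`.
#' @export
tukey_kramer <- function(data, alpha = 0.05) {
  check_group_data(data)
  g <- split(data$value, data$group)
  k <- length(g)
  ns <- vapply(g, length, numeric(1))
  means <- vapply(g, mean, numeric(1))
  N <- sum(ns)
  df <- N - k
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1))) / df
  qc <- qtukey(1 - alpha, k, df)
  n_h <- k / sum(1 / ns)

  pair_idx <- utils::combn(k, 2)
  pairs <- tibble(
    group1 = names(g)[pair_idx[1, ]],
    group2 = names(g)[pair_idx[2, ]],
    diff = unname(means[pair_idx[2, ]] - means[pair_idx[1, ]]),
    se = unname(sqrt(mse / 2 * (1 / ns[pair_idx[1, ]] + 1 / ns[pair_idx[2, ]])))
  ) |>
    mutate(lwr = .data$diff - qc * .data$se,
           upr = .data$diff + qc * .data$se,
           p.adj = ptukey(abs(.data$diff) / .data$se, k, df, lower.tail = FALSE),
           significant = .data$lwr > 0 | .data$upr < 0)

  hw <- (qc / 2) * sqrt(mse / 2 * (1 / ns + 1 / n_h))
  groups <- tibble(group = names(g), mean = unname(means), n = unname(ns),
                   lwr = unname(means - hw), upr = unname(means + hw))

  structure(list(pairs = pairs, groups = groups, alpha = alpha,
                 q_crit = qc, df = df, mse = mse),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("<tukey_result> k = %d groups, df = %d, q = %.4f (alpha = %g)\n",
              nrow(x$groups), x$df, x$q_crit, x$alpha))
  print(x$pairs)
  invisible(x)
}

#' @rdname tukey_kramer
#' @param x,object A `tukey_result`.
#' @param ... Unused.
#' @export
tidy.tukey_result <- function(x, ...) x$pairs

#' @rdname tukey_kramer
#' @export
glance.tukey_result <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), df = x$df, q_crit = x$q_crit,
         mse = x$mse, alpha = x$alpha,
         n_significant = sum(x$pairs$significant))
}

#' @export
autoplot.tukey_result <- function(object, ...) {
  ggplot(object$groups, aes(x = .data$group, y = .data$mean)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$lwr, ymax = .data$upr), width = 0.2) +
    labs(x = "group", y = "mean with comparison interval",
         title = "Tukey-Kramer comparison intervals",
         subtitle = "Disjoint intervals indicate a significant difference") +
    theme_minimal()
}

#' Linear regression of a parameter against temperature
#'
#' Ordinary least squares of `value ~ Ts` with the coefficient of
#' determination, the per-parameter temperature trend used to select
#' well-correlated texture parameters.
#'
#' @param values Numeric response.
#' @param Ts Substrate temperatures, °C.
#' @return One-row tibble: `slope`, `intercept`, `r2`, `n`.
#' @export
regress_vs_temperature <- function(values, Ts) {
  ok <- complete.cases(values, Ts)
  values <- values[ok]; Ts <- Ts[ok]
  if (length(values) < 3) abort("Need at least 3 points.")
  if (length(unique(Ts)) < 2) abort("`Ts` is constant.")
  fit <- lm(values ~ Ts)
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, n = length(values))
}

#' Bilinear (degree 1-1) regression against temperature and volume
#'
#' Least-squares plane `value ~ c0 + cT * Ts + cV * V`: the first-order
#' polynomial surface in temperature and initial volume. Being a model
#' nesting the temperature-only regression, its r-squared is never
#' smaller on the same data.
#'
#' @param values Numeric response.
#' @param Ts Substrate temperatures, °C.
#' @param V Initial drop volumes, ul.
#' @return One-row tibble: `c0`, `cT`, `cV`, `r2`, `n`.
#' @export
regress_plane_TV <- function(values, Ts, V) {
  ok <- complete.cases(values, Ts, V)
  values <- values[ok]; Ts <- Ts[ok]; V <- V[ok]
  if (length(values) < 4) abort("Need at least 4 points.")
  X <- cbind(1, Ts, V)
  if (qr(X)$rank < 3) abort("Design matrix is rank deficient.")
  fit <- lm(values ~ Ts + V)
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(fit$residuals^2) / ss_tot
  tibble(c0 = unname(coef(fit)[1]), cT = unname(coef(fit)[2]),
         cV = unname(coef(fit)[3]), r2 = r2, n = length(values))
}

#' Per-parameter significance table
#'
#' Runs one-way ANOVA and Tukey-Kramer across temperature groups for
#' every texture parameter in a study table — the machine-readable
#' analogue of a per-parameter p-value table with a pairwise
#' significance matrix.
#'
#' @param reports A data frame with a `Ts_C` column and one column per
#'   texture parameter (see [texture_parameter_names()]); typically the
#'   per-drop output of [run_study()].
#' @param parameters Parameter columns to analyse (default: the 16
#'   selected parameters present in `reports`).
#' @param alpha Significance level (default 0.05).
#' @return A `significance_table`: list with `anova` (tibble: parameter,
#'   F, p-value, significant) and `pairwise` (tibble: parameter, group
#'   pair, significant flag).
#' @export
significance_table <- function(reports, parameters = NULL, alpha = 0.05) {
  if (is.null(parameters)) {
    parameters <- intersect(texture_parameter_names(), names(reports))
  }
  if (length(parameters) == 0) abort("No parameter columns found.")
  counts <- table(reports$Ts_C)
  if (any(counts < 2)) abort("Need at least 2 drops per temperature.")

  rows <- map(parameters, function(p) {
    d <- tibble(value = reports[[p]], group = reports$Ts_C)
    d <- d[complete.cases(d), ]
    an <- one_way_anova(d)
    tk <- tukey_kramer(d, alpha = alpha)
    list(anova = mutate(an, parameter = p, .before = 1),
         pairwise = mutate(tk$pairs[, c("group1", "group2", "significant")],
                           parameter = p, .before = 1))
  })
  anova_tab <- list_rbind(map(rows, "anova")) |>
    mutate(significant = .data$p.value < alpha)
  structure(list(anova = anova_tab,
                 pairwise = list_rbind(map(rows, "pairwise")),
                 alpha = alpha),
            class = "significance_table")
}

#' @export
print.significance_table <- function(x, ...) {
  cat(sprintf("<significance_table> %d parameters at alpha = %g\n",
              nrow(x$anova), x$alpha))
  print(x$anova)
  invisible(x)
}

#' @rdname significance_table
#' @param x A `significance_table`.
#' @param ... Unused.
#' @export
tidy.significance_table <- function(x, ...) x$anova

#' Write a significance table as CSV files
#'
#' `anova.csv` mirrors the per-parameter p-value table; `pairwise.csv`
#' is the pairwise significance matrix as booleans.
#'
#' @param x A `significance_table`.
#' @param dir Output directory.
#' @export
write_significance_table <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$anova, file.path(dir, "anova.csv"), row.names = FALSE, quote = FALSE)
  write.csv(x$pairwise, file.path(dir, "pairwise.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
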