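test_that("one-way ANOVA reduces to the pooled t-test for two groups", {
  set.seed(21)
  d <- tibble::tibble(value = c(rnorm(12, 0), rnorm(12, 0.8)),
                      group = rep(c("a", "b"), each = 12))
  an <- one_way_anova(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(an$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(an$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA handles equal means and degenerate data by convention", {
  d <- tibble::tibble(value = rep(c(1, 2, 3), 4),
                      group = rep(c("a", "b", "c", "d"), each = 3))
  an <- one_way_anova(d)
  expect_equal(an$statistic, 0, tolerance = 1e-10)
  expect_equal(an$p.value, 1, tolerance = 1e-10)

  dz <- tibble::tibble(value = rep(5, 8), group = rep(c("a", "b"), each = 4))
  expect_warning(anz <- one_way_anova(dz), "convention")
  expect_equal(anz$p.value, 1)
  expect_true(anz$degenerate)

  expect_error(one_way_anova(tibble::tibble(value = 1:3, group = "a")), "2 groups")
})

test_that("Tukey-Kramer agrees with the reference HSD implementation", {
  set.seed(22)
  d <- tibble::tibble(value = rnorm(60) + rep(c(0, 0.5, 1, 2), each = 15),
                      group = rep(c("g1", "g2", "g3", "g4"), each = 15))
  tk <- tukey_kramer(d)
  ref <- TukeyHSD(aov(value ~ factor(group), data = d))[[1]]
  key <- paste(tk$pairs$group2, tk$pairs$group1, sep = "-")
  expect_equal(tk$pairs$diff, unname(ref[key, "diff"]), tolerance = 1e-9)
  expect_equal(tk$pairs$lwr, unname(ref[key, "lwr"]), tolerance = 1e-9)
  expect_equal(tk$pairs$upr, unname(ref[key, "upr"]), tolerance = 1e-9)
  expect_equal(tk$pairs$p.adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
})

test_that("disjoint comparison intervals coincide with pairwise significance", {
  # balanced design: the graphical rule must equal the pairwise test
  set.seed(23)
  for (rep_i in 1:5) {
    d <- tibble::tibble(value = rnorm(72) + rep(c(0, 0.3, 0.6, 1), each = 18),
                        group = rep(c("23", "37", "60", "90"), each = 18))
    tk <- tukey_kramer(d)
    gi <- tk$groups
    for (r in seq_len(nrow(tk$pairs))) {
      g1 <- gi[gi$group == tk$pairs$group1[r], ]
      g2 <- gi[gi$group == tk$pairs$group2[r], ]
      disjoint <- g1$upr < g2$lwr || g2$upr < g1$lwr
      expect_identical(disjoint, tk$pairs$significant[r])
    }
  }
})

test_that("Tukey-Kramer reduces to the two-sample t-test at k = 2", {
  set.seed(24)
  d <- tibble::tibble(value = c(rnorm(10), rnorm(10, 1)),
                      group = rep(c("a", "b"), each = 10))
  tk <- tukey_kramer(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  expect_equal(tk$pairs$p.adj, tt$p.value, tolerance = 1e-8)
  expect_identical(tk$pairs$significant, tt$p.value < 0.05)
})

test_that("strong separation is detected and equal means are not", {
  set.seed(25)
  d <- tibble::tibble(
    value = c(rnorm(18, 0), rnorm(18, 0), rnorm(18, 5), rnorm(18, 10)),
    group = rep(c("a", "b", "c", "d"), each = 18))
  tk <- tukey_kramer(d)
  ab <- tk$pairs$group1 == "a" & tk$pairs$group2 == "b"
  expect_false(tk$pairs$significant[ab])
  expect_true(all(tk$pairs$significant[!ab]))
})

test_that("temperature regressions equal the normal-equations solutions", {
  set.seed(26)
  Ts <- rep(c(23, 37, 60, 90), each = 18)
  y <- 0.05 * Ts + rnorm(72, 0, 0.3)
  fit <- regress_vs_temperature(y, Ts)
  X <- cbind(1, Ts)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2], tolerance = 1e-10)

  exact <- regress_vs_temperature(2 + 0.1 * Ts, Ts)
  expect_equal(exact$r2, 1, tolerance = 1e-12)

  # pure noise: r2 stays near zero at n = 72
  noise <- regress_vs_temperature(rnorm(72), Ts)
  expect_lt(noise$r2, 0.2)
  expect_error(regress_vs_temperature(y, rep(23, 72)), "constant")
})

test_that("bilinear regression recovers planes and nests the linear model", {
  set.seed(27)
  Ts <- rep(c(23, 37, 60, 90), each = 18)
  V <- 11 + rnorm(72, 0, 0.5)
  y_exact <- 1 + 0.2 * Ts - 0.5 * V
  pf <- regress_plane_TV(y_exact, Ts, V)
  expect_equal(c(pf$c0, pf$cT, pf$cV), c(1, 0.2, -0.5), tolerance = 1e-9)
  expect_equal(pf$r2, 1, tolerance = 1e-12)

  y <- 0.2 * Ts - 0.5 * V + rnorm(72, 0, 0.5)
  X <- cbind(1, Ts, V)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  pn <- regress_plane_TV(y, Ts, V)
  expect_equal(c(pn$c0, pn$cT, pn$cV), as.numeric(beta), tolerance = 1e-9)
  expect_gte(pn$r2, regress_vs_temperature(y, Ts)$r2)
  expect_error(regress_plane_TV(y, Ts, Ts), "rank")
})

test_that("significance table flags programmed effects and spares null columns", {
  set.seed(28)
  Ts <- rep(c(23, 37, 60, 90), each = 18)
  # null column built with exactly equal group means (within-group noise only)
  null_vals <- as.vector(sapply(1:4, function(i) scale(rnorm(18), scale = FALSE)))
  reports <- tibble::tibble(
    Ts_C = Ts,
    Sq = 0.05 * Ts + rnorm(72, 0, 0.3),   # programmed effect
    Sda = null_vals                        # programmed zero effect
  )
  st <- significance_table(reports, parameters = c("Sq", "Sda"))
  p_sq <- st$anova$p.value[st$anova$parameter == "Sq"]
  p_null <- st$anova$p.value[st$anova$parameter == "Sda"]
  expect_lt(p_sq, 1e-6)
  expect_equal(p_null, 1, tolerance = 1e-9)

  # permuting the temperature labels destroys the effect
  perm <- reports
  perm$Ts_C <- sample(perm$Ts_C)
  stp <- significance_table(perm, parameters = "Sq")
  expect_gt(stp$anova$p.value, 1e-6)

  d <- tempfile()
  write_significance_table(st, d)
  expect_true(file.exists(file.path(d, "anova.csv")))
  expect_true(file.exists(file.path(d, "pairwise.csv")))
})
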