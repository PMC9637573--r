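test_that("spherical-cap volume matches closed forms and a quadrature oracle", {
  expect_equal(spherical_cap_volume(2, 90), 2 * pi / 3, tolerance = 1e-12)
  # V ~ theta: vanishes linearly as the cap flattens
  expect_lt(spherical_cap_volume(3, 0.01), 1e-3)
  expect_lt(spherical_cap_volume(3, 1e-4), 1e-5)

  # solid-of-revolution oracle: V = int pi x(z)^2 dz over the cap
  cap_oracle <- function(D, theta) {
    r <- D / 2
    th <- theta * pi / 180
    h <- r * tan(th / 2)
    Rc <- (r^2 + h^2) / (2 * h)
    z0 <- h - Rc
    stats::integrate(function(z) pi * (Rc^2 - (z - z0)^2), 0, h,
                     rel.tol = 1e-12)$value
  }
  for (case in list(c(3, 50), c(2, 30), c(5, 120))) {
    expect_equal(spherical_cap_volume(case[1], case[2]),
                 cap_oracle(case[1], case[2]), tolerance = 1e-9)
  }

  # strictly increasing in both arguments
  thetas <- seq(10, 170, 10)
  expect_true(all(diff(spherical_cap_volume(3, thetas)) > 0))
  Ds <- seq(1, 6, 0.5)
  expect_true(all(diff(spherical_cap_volume(Ds, 50)) > 0))
  expect_error(spherical_cap_volume(-1, 50))
  expect_error(spherical_cap_volume(3, 190))
})

test_that("contact-angle extraction recovers cap angles and is scale invariant", {
  expect_equal(unlist(extract_contact_angle(cap_profile(4.8, 50))),
               c(theta_l_deg = 50, theta_r_deg = 50), tolerance = 0.5 / 50)
  expect_equal(unlist(extract_contact_angle(cap_profile(2, 90))),
               c(theta_l_deg = 90, theta_r_deg = 90), tolerance = 0.5 / 90)
  # near-flat drop: angle near zero
  expect_lt(extract_contact_angle(cap_profile(4, 5))$theta_l_deg, 6)

  # uniform scaling leaves angles unchanged
  prof <- cap_profile(3, 65)
  scaled <- tibble::tibble(x_mm = prof$x_mm * 7.3, z_mm = prof$z_mm * 7.3)
  expect_equal(unlist(extract_contact_angle(prof)),
               unlist(extract_contact_angle(scaled)), tolerance = 1e-9)
})

test_that("mirroring a profile swaps the left and right contact angles", {
  # shear an exact cap to make the two contact angles differ
  prof <- cap_profile(3, 60)
  sheared <- tibble::tibble(x_mm = prof$x_mm + 0.25 * prof$z_mm,
                            z_mm = prof$z_mm)
  mirrored <- tibble::tibble(x_mm = -sheared$x_mm, z_mm = sheared$z_mm)
  a <- extract_contact_angle(sheared)
  b <- extract_contact_angle(mirrored)
  expect_gt(abs(a$theta_l_deg - a$theta_r_deg), 2)  # genuinely asymmetric
  expect_equal(a$theta_l_deg, b$theta_r_deg, tolerance = 1e-6)
  expect_equal(a$theta_r_deg, b$theta_l_deg, tolerance = 1e-6)
})

test_that("volume-shrinkage slope is exact on lines and honest on noisy data", {
  t <- seq(0, 1000, 10)
  s <- droplet_series(t, 11 - 0.01 * t, rep(1, length(t)),
                      rep(50, length(t)), rep(50, length(t)),
                      rep(4, length(t)), Ts = 23)
  fit <- volume_shrinkage_slope(s)
  expect_equal(fit$slope, -0.01, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # line then plateau: the growing window leaks only slightly past the
  # kink at the default threshold, and excludes the plateau at a strict one
  V2 <- ifelse(t <= 600, 11 - 0.01 * t, 5)
  s2 <- droplet_series(t, V2, rep(1, length(t)), rep(50, length(t)),
                       rep(50, length(t)), rep(4, length(t)), Ts = 23)
  fit2 <- volume_shrinkage_slope(s2)
  expect_equal(fit2$slope, -0.01, tolerance = 0.11)
  strict <- volume_shrinkage_slope(s2, r2_min = 0.9999)
  expect_equal(strict$slope, -0.01, tolerance = 0.005)
  expect_lte(strict$window[2], 620)

  # Gaussian noise: slope within 3 standard errors (OLS sampling theory)
  set.seed(11)
  V3 <- 11 - 0.01 * t + rnorm(length(t), 0, 0.05)
  s3 <- droplet_series(t, V3, rep(1, length(t)), rep(50, length(t)),
                       rep(50, length(t)), rep(4, length(t)), Ts = 23)
  fit3 <- volume_shrinkage_slope(s3)
  k <- fit3$n
  se <- 0.05 / sqrt(sum((t[1:k] - mean(t[1:k]))^2))
  expect_lt(abs(fit3$slope - (-0.01)), 3 * se)

  expect_error(volume_shrinkage_slope(s[1:5, ]), "10")
})

test_that("volume-diameter fit recovers power laws", {
  D <- seq(2, 6, length.out = 10)
  recs <- tibble::tibble(V0_ul = 0.1 * D^3, D_mm = D, Ts_C = 23)
  fit <- fit_volume_diameter(recs)
  expect_equal(fit$table$k, 3, tolerance = 1e-10)
  expect_equal(fit$table$c, 0.1, tolerance = 1e-10)
  expect_equal(fit$table$r2, 1, tolerance = 1e-12)
  expect_equal(predict_volume(fit, 4, 23), 0.1 * 64, tolerance = 1e-9)

  # spherical caps of fixed angle scale as D^3
  recs2 <- tibble::tibble(V0_ul = spherical_cap_volume(D, 50), D_mm = D, Ts_C = 37)
  expect_equal(fit_volume_diameter(recs2)$table$k, 3, tolerance = 1e-8)

  # noisy data matches the OLS-on-logs normal equations
  set.seed(3)
  lv <- log(0.1) + 3 * log(D) + rnorm(10, 0, 0.05)
  recs3 <- tibble::tibble(V0_ul = exp(lv), D_mm = D, Ts_C = 60)
  x <- log(D)
  k_hat <- sum((x - mean(x)) * (lv - mean(lv))) / sum((x - mean(x))^2)
  fit3 <- fit_volume_diameter(recs3)
  expect_equal(fit3$table$k, k_hat, tolerance = 1e-10)
  expect_error(fit_volume_diameter(tibble::tibble(V0_ul = -1, D_mm = 2, Ts_C = 23)))
})

test_that("dome detection finds programmed onsets and ignores monotone decay", {
  t <- seq(0, 1200, 5)
  s <- droplet_series(t, 11 * (1 - t / 1200), 1.1 * (1 - t / 1200),
                      rep(50, length(t)), rep(50, length(t)),
                      rep(4.8, length(t)), Ts = 23)
  expect_true(is.na(detect_dome_formation(s)))

  rec <- fake_record(Ts = 37, V0 = 11)
  s37 <- generate_droplet_series(rec, noise_frac = 0)
  onset <- detect_dome_formation(s37)
  expect_false(is.na(onset))
  expect_equal(onset, 900, tolerance = 0.1)

  for (Ts in c(60, 90)) {
    sh <- generate_droplet_series(fake_record(Ts = Ts), noise_frac = 0)
    on_h <- detect_dome_formation(sh)
    expect_lt(on_h, 0.1 * max(sh$t_s))
  }
})

test_that("generated series respect CCR mode and round-trip through CSV", {
  rec <- fake_record(Ts = 23)
  s <- generate_droplet_series(rec, noise_frac = 0)
  expect_true(all(abs(s$D_mm - s$D_mm[1]) < 1e-9))
  path <- tempfile(fileext = ".csv")
  write_droplet_series(s, path)
  s2 <- read_droplet_series(path)
  expect_equal(attr(s2, "Ts"), 23)
  expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-6)
})
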