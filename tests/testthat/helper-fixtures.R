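# Shared fixtures, all built in code.

# a minimal study record
fake_record <- function(Ts = 23, V0 = 11, seed = 101) {
  list(drop_id = "d000", Ts_C = Ts, V0_ul = V0, replicate = 1L, seed = seed)
}

# disc mask of radius r (px) centred in an n x n grid, as a height bump
disc_map <- function(n = 64, r = 20, h = 1, pitch = 1) {
  ctr <- (n + 1) / 2
  rr <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  height_map(ifelse(rr <= r, h, 0), lateral_pitch = pitch)
}

# axis-aligned ellipse bump (semi-axes a, b in px)
ellipse_map <- function(n = 96, a = 30, b = 15, h = 1, pitch = 1) {
  ctr <- (n + 1) / 2
  u <- outer(1:n - ctr, rep(1, n))
  v <- t(u)
  height_map(ifelse((u / a)^2 + (v / b)^2 <= 1, h, 0), lateral_pitch = pitch)
}

# two-level step surface: left half at +h, right half at -h (zero mean)
step_map <- function(n = 100, h = 1) {
  z <- matrix(rep(c(h, -h), each = n * n / 2), n, n)
  height_map(z, lateral_pitch = 1)
}

# even-symmetric cosine sheet: zero-mean, zero least-squares plane,
# whole periods, >= 64 samples per period
cosine_map <- function(n = 256, A = 2, period = 64) {
  ctr <- (n + 1) / 2
  z <- A * outer(cos(2 * pi * (1:n - ctr) / period), rep(1, n))
  height_map(z, lateral_pitch = 1)
}

# noiseless edge-centre series with a programmed dT(t)
programmed_ecs <- function(t, dT, T_center = 30) {
  structure(
    tibble::tibble(t_s = t, T_tpcl = T_center + dT, T_center = T_center,
                   dT = dT),
    class = c("edge_center_series", class(tibble::tibble()))
  )
}
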