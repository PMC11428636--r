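test_that("features of a pure sine: peak, min, pulse pressure, no notch", {
  tt <- seq(0, 1, length.out = 129)[1:128]
  w <- pressure_waveform(tt, 100 + 15 * sin(2 * pi * tt), 1)
  f <- extract_features(w)
  expect_equal(f$systolic_peak$value, max(w$values))
  expect_equal(f$diastolic_min$value, min(w$values))
  expect_equal(f$pulse_pressure, max(w$values) - min(w$values))
  expect_null(f$dicrotic_notch)
  expect_equal(f$mean_pressure, 100, tolerance = 1e-6)
})

test_that("constant waveform yields absent notch and zero pulse pressure", {
  tt <- seq(0, 1, length.out = 33)[1:32]
  w <- pressure_waveform(tt, rep(90, 32), 1)
  expect_warning(f <- extract_features(w), "constant")
  expect_null(f$dicrotic_notch)
  expect_equal(f$pulse_pressure, 0)
})

test_that("planted landmarks are recovered exactly at sample resolution", {
  for (s in c(1, 7, 19)) {
    syn <- synth_pressure_waveform(synth_config(seed = s))
    f <- extract_features(syn$waveform)
    expect_identical(f$systolic_peak$value, syn$truth$sbp)
    expect_identical(f$diastolic_min$value, syn$truth$dbp)
    expect_identical(f$systolic_peak$time, syn$truth$t_peak)
    expect_identical(f$dicrotic_notch$time, syn$truth$notch$time)
    expect_identical(f$end_diastolic_pressure,
                     syn$truth$end_diastolic_pressure)
  }
})

test_that("notch detection is consistent across sampling rates", {
  syn_fine <- synth_pressure_waveform(synth_config(seed = 3, n_samples = 1000))
  syn_coarse <- synth_pressure_waveform(synth_config(seed = 3, n_samples = 250))
  f1 <- extract_features(syn_fine$waveform)
  f2 <- extract_features(syn_coarse$waveform)
  expect_lt(abs(f1$dicrotic_notch$time - f2$dicrotic_notch$time),
            1 / 250 + 1e-12)
})

test_that("feature values are invariant to a circular shift of the origin", {
  syn <- synth_pressure_waveform(synth_config(seed = 11))
  w <- syn$waveform
  k <- 333
  v2 <- c(w$values[(k + 1):length(w$values)], w$values[1:k])
  w2 <- pressure_waveform(w$times, v2, w$period_T)
  f1 <- extract_features(w)
  f2 <- extract_features(w2)
  expect_identical(f1$systolic_peak$value, f2$systolic_peak$value)
  expect_identical(f1$diastolic_min$value, f2$diastolic_min$value)
})

test_that("waveform_difference: exact cases and the |A sin| analytic mean", {
  syn <- synth_pressure_waveform(synth_config(seed = 2))
  a <- syn$waveform
  expect_equal(waveform_difference(a, a), list(mean_abs_diff = 0,
                                               max_abs_diff = 0))
  b <- a; b$values <- a$values + 4.5
  d <- waveform_difference(a, b)
  expect_equal(d$mean_abs_diff, 4.5)
  expect_equal(d$max_abs_diff, 4.5)
  A <- 2
  b2 <- a; b2$values <- a$values + A * sin(2 * pi * a$times / a$period_T)
  expect_equal(waveform_difference(a, b2)$mean_abs_diff, 2 * A / pi,
               tolerance = 1e-3)
  bT <- pressure_waveform(a$times * 1.5, a$values, a$period_T * 1.5)
  expect_error(waveform_difference(a, bT), "period")
})

test_that("waveform_difference is a pseudometric on random triples", {
  set.seed(8)
  tt <- seq(0, 1, length.out = 65)[1:64]
  mk <- function() pressure_waveform(tt, 100 + cumsum(stats::rnorm(64, sd = 0.5)) -
                                       seq(0, 1, length.out = 64) * 0, 1)
  for (i in 1:5) {
    a <- mk(); b <- mk(); c_ <- mk()
    dab <- waveform_difference(a, b)$mean_abs_diff
    dba <- waveform_difference(b, a)$mean_abs_diff
    expect_equal(dab, dba)
    dac <- waveform_difference(a, c_)$mean_abs_diff
    dbc <- waveform_difference(b, c_)$mean_abs_diff
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("percent_error: identity, uniform scaling, planted envelope", {
  syn <- synth_pressure_waveform(synth_config(seed = 4))
  ref <- syn$waveform
  expect_equal(percent_error(ref, ref), 0)
  sim <- ref; sim$values <- 1.05 * ref$values
  expect_equal(percent_error(sim, ref), 5, tolerance = 1e-12)
  # planted relative noise envelope of known mean absolute size
  set.seed(101)
  eps <- 0.02 * sample(c(-1, 1), length(ref$values), TRUE)
  sim2 <- ref; sim2$values <- ref$values * (1 + eps)
  expect_equal(percent_error(sim2, ref), 2, tolerance = 1e-3)
  neg <- ref; neg$values <- ref$values - 200
  expect_error(percent_error(ref, neg), "positive")
})

test_that("delta_p: zero, constant offset, planted phase lag peak", {
  syn <- synth_pressure_waveform(synth_config(seed = 6))
  a <- syn$waveform
  d0 <- delta_p(a, a)
  expect_true(all(d0$dp_waveform$values == 0))
  b <- a; b$values <- a$values - 2.5; b$location <- "aortic arch"
  d1 <- delta_p(a, b)
  expect_equal(d1$mean_dp, 2.5)
  # phase-lagged pair: peak matches brute-force evaluation on the grid
  lag <- 0.04
  fb <- stats::approx(c(a$times, a$period_T), c(a$values, a$values[1]),
                      xout = (a$times - lag) %% a$period_T)$y
  b2 <- pressure_waveform(a$times, fb, a$period_T, "aortic arch")
  d2 <- delta_p(a, b2)
  tg <- seq(0, a$period_T, length.out = 1001)[1:1000]
  fa_g <- stats::approx(c(a$times, a$period_T), c(a$values, a$values[1]), tg)$y
  fb_g <- stats::approx(c(b2$times, b2$period_T), c(b2$values, b2$values[1]), tg)$y
  dd <- fa_g - fb_g
  expect_equal(d2$peak_dp, dd[which.max(abs(dd))])
})

test_that("systolic/diastolic table recovers planted pressures per member", {
  ws <- lapply(1:4, function(s) {
    syn <- synth_pressure_waveform(synth_config(seed = s, sbp = 110 + 2 * s,
                                                dbp = 70 + s))
    syn$waveform$location <- paste0("member_", s)
    syn$waveform
  })
  tab <- systolic_diastolic_table(ws)
  expect_equal(tab$systolic_mmHg, 110 + 2 * (1:4))
  expect_equal(tab$diastolic_mmHg, 70 + (1:4))
  expect_error(systolic_diastolic_table(list()), "empty")
})

test_that("mmHg/Pa conversion round-trips at the fixed factor", {
  x <- c(0.4, 5, 80, 120, 250)
  expect_equal(pa_to_mmhg(mmhg_to_pa(x)), x, tolerance = 1e-12)
  expect_equal(mmhg_to_pa(1), 133.322)
})
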