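test_that("introduction peak is the max over the first 100 s, window bounded", {
  fz_v <- rep(0, 25 * 300)
  fz_v[25 * 60] <- 4.2          # spike at t = 60 - 0.04 s, i.e. intro + 30 s
  fz <- make_fz(fz_v)
  expect_equal(introduction_peak(fz, intro_time = 30), 4.2)

  # a spike beyond intro + 100 s is excluded
  fz_v2 <- rep(0, 25 * 300); fz_v2[25 * 200] <- 9
  expect_equal(introduction_peak(make_fz(fz_v2), intro_time = 30), 0)

  # monotone decreasing trace peaks at the introduction time
  dec <- make_fz(seq(5, 0, length.out = 2501))
  expect_equal(as.numeric(introduction_peak(dec, intro_time = 10)),
               approx(dec$time, dec$fz, 10)$y, tolerance = 1e-2)

  expect_error(introduction_peak(fz, intro_time = 1e5), "outside")
})

test_that("presentation peak averages within-bout maxima (brute-force agreement)", {
  set.seed(12)
  fz <- make_fz(rnorm(5000) - 5)          # all-negative Fz
  b <- make_bouts(seq(10, 170, by = 40), seq(20, 180, by = 40),
                  behavior = "introduction")
  got <- presentation_peak(fz, b)
  oracle <- mean(vapply(seq_len(nrow(b)), function(i) {
    max(fz$fz[fz$time >= b$onset_s[i] & fz$time < b$offset_s[i]])
  }, numeric(1)))
  expect_equal(got, oracle)
  expect_error(presentation_peak(fz, b[0, ]), "no presentations")

  # [1,2,3,4,5] -> 3 via a staircase of spikes
  v <- rep(-10, 5000)
  for (k in 1:5) v[25 * (10 + 40 * (k - 1)) + 13] <- k
  expect_equal(presentation_peak(make_fz(v), b), 3)
})

test_that("behavior mean is bout-weighted, not sample-weighted", {
  fz <- make_fz(rep(2.2, 1000))
  b <- make_bouts(c(1, 10), c(3, 12))
  expect_equal(behavior_mean_fz(fz, b), 2.2)

  # bout means 0 and 2 with very different durations still average to 1
  v <- rep(0, 2500)
  v[seq(251, 750)] <- 0          # bout 1: [10, 30), mean 0
  v[seq(1001, 1050)] <- 2        # bout 2: [40, 42), mean 2
  b2 <- make_bouts(c(10, 40), c(30, 42))
  expect_equal(behavior_mean_fz(make_fz(v), b2), 1)
})

test_that("session mean matches direct summation", {
  v <- rep(c(1, -1), 500)
  fz <- make_fz(v)
  expect_equal(session_mean_fz(fz, c(0, 40)), 0)
  set.seed(3)
  fz2 <- make_fz(rnorm(1000))
  idx <- fz2$time >= 5 & fz2$time < 30
  expect_equal(session_mean_fz(fz2, c(5, 30)), sum(fz2$fz[idx]) / sum(idx))
  expect_error(session_mean_fz(fz2, c(500, 600)), "no samples")
})

test_that("trial responses: threshold, latency, and the Z >= 1 boundary", {
  # normalized ramp crossing 1 at 0.8 s after onset
  v <- rep(0, 1000)
  on_i <- 251                       # onset at 10 s
  ramp <- seq(0, 2, length.out = 51)  # reaches 1 at sample 26 -> 1.0 s... use index math
  v[on_i:(on_i + 50)] <- ramp
  fz <- make_fz(v)
  b <- make_bouts(10, 14)
  tr <- trial_responses(fz, b)
  expect_true(tr$trials$responded)
  # ramp hits 1 at sample on_i + 25 => 0.04 * 25 = 1.0 s
  expect_equal(tr$trials$latency_s, 1.0, tolerance = 0.04 + 1e-9)
  expect_equal(tr$percent_responsive, 100)
  expect_lte(tr$trials$latency_s, tr$trials$duration_s)
  expect_gte(tr$trials$latency_s, 0)

  # max normalized response 0.99 -> not responded, latency absent
  v2 <- rep(0, 1000); v2[on_i:(on_i + 50)] <- 0.99
  tr2 <- trial_responses(make_fz(v2), b)
  expect_false(tr2$trials$responded)
  expect_true(is.na(tr2$trials$latency_s))
  expect_equal(tr2$percent_responsive, 0)

  # normalization subtracts the signal at time 0: a constant-offset trace
  # never responds
  tr3 <- trial_responses(make_fz(rep(5, 1000)), b)
  expect_false(tr3$trials$responded)

  # sub-sample bout is skipped with a warning
  bshort <- make_bouts(10, 10.001)
  expect_warning(trs <- trial_responses(fz, bshort), "skipped")
  expect_equal(trs$n_skipped, 1L)
})

test_that("implanted response flags and crossing times are recovered from the latent Fz", {
  cfg <- sim_config_foxp2(seed = 13, paradigm = "freely_moving",
                          stimuli = "male", amplitude = c(male = 0.15),
                          response_prob = c(male = 0.5), attack_prob = 0,
                          stimulus_duration = 600)
  s <- simulate_photometry_session(cfg)
  tr <- trial_responses(s$truth$fz_latent, s$bouts)
  tb <- s$truth$bouts
  expect_equal(tr$trials$responded, tb$responded)
  ok <- !is.na(tb$crossing_s)
  expect_true(all(abs(tr$trials$latency_s[ok] -
                        (tb$crossing_s[ok] - tb$onset_s[ok])) <= 1 / cfg$fs + 1e-9))
})

test_that("preference index follows the printed formula and its bounds", {
  expect_equal(preference_index(c(male = 1, female = 0, pup = 0), "male")$pi, 1)
  expect_equal(preference_index(c(male = 0.7, female = 0.7, pup = 0.7), "male")$pi, 0)
  expect_equal(preference_index(c(male = 2, female = 1, pup = 1), "male")$pi, 1 / 3)

  z0 <- preference_index(c(male = 0, female = 0, pup = 0), "male")
  expect_false(z0$defined)
  expect_true(is.na(z0$pi))
  expect_error(preference_index(c(male = 1, female = 2), "male"), "pup")

  set.seed(8)
  for (i in 1:200) {
    z <- setNames(rnorm(3, 0, 2), c("male", "female", "pup"))
    for (tg in c("male", "female", "pup")) {
      pi1 <- preference_index(z, tg)
      if (pi1$defined) {
        expect_lte(abs(pi1$pi), 1)
        pi2 <- preference_index(z * 3.7, tg)   # scale invariance
        expect_equal(pi2$pi, pi1$pi, tolerance = 1e-12)
      }
    }
  }
})

test_that("tuned simulations recover class-specific preference", {
  sf <- simulate_photometry_session(
    sim_config_foxp2(seed = 17, paradigm = "freely_moving"))
  fzf <- preprocess_trace(sf$trace)
  zf <- stimulus_response_summary(fzf, merge_labels(sf$bouts))
  expect_gt(preference_index(zf, "male")$pi, 0)
  expect_lt(preference_index(zf, "female")$pi, 0)
  expect_lt(preference_index(zf, "pup")$pi, 0)

  sd1 <- simulate_photometry_session(
    sim_config_dbx1(seed = 17, paradigm = "freely_moving"))
  fzd <- preprocess_trace(sd1$trace)
  zd <- stimulus_response_summary(fzd, merge_labels(sd1$bouts))
  expect_true(all(zd > 0))
})
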