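test_that("generated sessions are deterministic in (config, seed)", {
  cfg <- sim_config_foxp2(seed = 9, paradigm = "freely_moving",
                          stimulus_duration = 120)
  a <- simulate_photometry_session(cfg)
  b <- simulate_photometry_session(cfg)
  expect_identical(a$trace$f_raw, b$trace$f_raw)
  expect_identical(as.data.frame(a$bouts), as.data.frame(b$bouts))
  expect_identical(a$truth$bouts$responded, b$truth$bouts$responded)
})

test_that("head-fixed schedule: five 10-s presentations per stimulus, 40-s gaps, 5-min breaks", {
  cfg <- sim_config_foxp2(seed = 1, paradigm = "head_fixed")
  s <- simulate_photometry_session(cfg)
  bt <- as.data.frame(s$bouts)
  for (stim in c("male", "female", "pup", "object")) {
    pres <- bt[bt$stimulus == stim, ]
    expect_equal(nrow(pres), 5L)
    expect_equal(pres$offset_s - pres$onset_s, rep(10, 5), tolerance = 1 / cfg$fs)
    expect_equal(diff(pres$onset_s), rep(50, 4))
  }
  # >= 5 min between the last presentation of one stimulus and the next block
  ends <- tapply(bt$offset_s, bt$stimulus, max)
  starts <- tapply(bt$onset_s, bt$stimulus, min)
  ord <- names(sort(starts))
  gaps <- starts[ord][-1] - ends[ord][-length(ord)]
  expect_true(all(gaps >= 300))
})

test_that("zero tuning amplitude leaves only drift plus noise", {
  cfg <- sim_config(seed = 4, paradigm = "head_fixed", stimuli = "male",
                    amplitude = c(male = 0), response_prob = c(male = 1),
                    noise_sd = 0)
  s <- simulate_photometry_session(cfg)
  expect_equal(s$trace$f_raw, s$truth$drift)
  expect_true(all(!s$truth$bouts$responded))
})

test_that("invalid configurations and schedules are rejected", {
  expect_error(sim_config(fs = 0), "positive")
  expect_error(sim_config(tau_off = -1), "positive")
  expect_error(sim_config(response_prob = c(male = 1.2, female = 0, pup = 0,
                                            object = 0)), "\\[0, 1\\]")
  cfg <- sim_config_foxp2(seed = 1, paradigm = "head_fixed", session_length = 100)
  expect_error(simulate_photometry_session(cfg), "does not cover")
})

test_that("every bout carries a ground-truth response flag", {
  s <- simulate_photometry_session(
    sim_config_dbx1(seed = 2, paradigm = "freely_moving", stimulus_duration = 120))
  expect_equal(nrow(s$truth$bouts), nrow(s$bouts))
  expect_type(s$truth$bouts$responded, "logical")
  expect_false(anyNA(s$truth$bouts$responded))
})

test_that("offset decay of the generator kernel matches tau_off * ln(10)", {
  # Foxp2-like: slow return (> 10 s); Dbx1-like: fast return (< 3 s)
  run_decay <- function(cfg, stim, post) {
    s <- simulate_photometry_session(cfg)
    fz <- preprocess_trace(s$trace)
    p <- compute_peth(fz, s$bouts, label = "introduction", stimulus = stim,
                      align = "offset", window_pre = 5, window_post = post,
                      bin = 0.2)
    peth_decay_time(p)
  }
  d_slow <- run_decay(sim_config_foxp2(seed = 5, paradigm = "head_fixed"),
                      "male", 38)
  d_fast <- run_decay(sim_config_dbx1(seed = 5, paradigm = "head_fixed"),
                      "female", 10)
  expect_gt(d_slow, 10)
  expect_lt(d_fast, 3)
  expect_equal(d_slow, 12 * log(10), tolerance = 0.2)
  expect_equal(d_fast, 1.2 * log(10), tolerance = 0.2)
})

test_that("count tables follow the requested multinomial", {
  one <- simulate_count_table(c(MeA = 1.0), 100, seed = 1)
  expect_equal(one$table$count, 100)

  expect_error(simulate_count_table(c(PA = 0.5, CoA = 0.4), 100, seed = 1),
               "sum to 1")

  a <- simulate_count_table(c(PA = 0.5, CoA = 0.3, BNST = 0.2), 5000, seed = 7)
  b <- simulate_count_table(c(PA = 0.5, CoA = 0.3, BNST = 0.2), 5000, seed = 7)
  expect_identical(a$table$count, b$table$count)

  emp <- a$table$count / 5000
  p <- c(0.5, 0.3, 0.2)
  expect_true(all(abs(emp - p) <= 3 * sqrt(p * (1 - p) / 5000)))
})

test_that("PSC sweep generation honors class, sign and latency", {
  expect_error(simulate_psc_sweeps(latency_ms = 0), "positive")

  none <- simulate_psc_sweeps(connection = "none", seed = 3)
  expect_false(detect_psc(none$sweeps$ACSF)$responsive)

  # noiseless threshold crossing of the alpha function starts at the true onset
  clean <- simulate_psc_sweeps(latency_ms = 4, noise_sd_pA = 0, seed = 2)
  ev <- detect_psc(clean$sweeps$ACSF)
  expect_true(ev$responsive)
  expect_equal(ev$latency_ms, 4, tolerance = 1000 / 20000 + 1e-9)

  # oIPSC at 0 mV is outward (positive)
  ipsc <- simulate_psc_sweeps(holding_mV = 0, noise_sd_pA = 0, seed = 2)
  m <- rowMeans(ipsc$sweeps$ACSF$current)
  expect_gt(max(m), 0)
  expect_gte(min(m), 0)
})
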