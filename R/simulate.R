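#' Simulation settings for synthetic photometry sessions
#'
#' Describes a bulk-calcium recording session with known ground truth: the
#' stimulus schedule (head-fixed: each stimulus presented five times for
#' 10 s with 40-s intervals and a 5-min break between stimuli; freely moving:
#' each intruder present for 10 min with investigation bouts inside), the
#' per-stimulus transient tuning, photobleaching drift and acquisition noise.
#'
#' The transient kernel is a saturating rise during a bout
#' (`1 - exp(-(t - onset)/tau_rise)`) followed after the bout offset by an
#' exponential decay with time constant `tau_off`. The two cell-class presets
#' differ in tuning and offset decay: a Foxp2-like configuration responds to
#' the male stimulus only and decays slowly (`tau_off = 12` s, so the
#' response falls to 10% of its offset value after `12 ln 10 = 27.6` s,
#' beyond 10 s), while a Dbx1-like configuration responds to all social
#' stimuli and decays fast (`tau_off = 1.2` s, 10% time `2.76` s, under 3 s).
#'
#' @param seed Integer seed; every generated observable is a deterministic
#'   function of the configuration including this seed.
#' @param fs Sampling rate, Hz.
#' @param paradigm `"head_fixed"` or `"freely_moving"`.
#' @param stimuli Character vector of stimuli presented, in order.
#' @param amplitude Named per-stimulus transient amplitude in fractional
#'   dF/F units (peak fluorescence change of a long bout).
#' @param response_prob Named per-stimulus probability that a given bout
#'   evokes a transient.
#' @param tau_rise Transient rise time constant, s.
#' @param tau_off Post-offset decay time constant, s.
#' @param bleach_amplitude Fractional fluorescence lost to photobleaching
#'   over `tau_bleach` (multiplicative exponential drift).
#' @param tau_bleach Bleaching time constant, s; defaults to the session
#'   length.
#' @param noise_sd Gaussian noise SD on the raw trace, raw units.
#' @param f0 Initial raw fluorescence level, arbitrary units.
#' @param n_presentations,presentation_dur,presentation_gap,stimulus_break
#'   Head-fixed schedule: presentations per stimulus (5), duration (10 s),
#'   inter-presentation interval (40 s), break between stimuli (300 s).
#' @param stimulus_duration,mean_bout,mean_gap,min_bout,attack_prob
#'   Freely-moving schedule: time each intruder spends in the cage (600 s),
#'   mean investigation bout length (s), mean gap between bouts (s), minimum
#'   bout length (s), and the probability that a male investigation bout is
#'   immediately followed by an attack.
#' @param intro_time Dead time before the first stimulus, s.
#' @param tail Recording time after the last scheduled event, s.
#' @param session_length Total session length, s; computed from the schedule
#'   when `NULL`. An explicit value too short for the schedule is an error.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, fs = 25,
                       paradigm = c("head_fixed", "freely_moving"),
                       stimuli = c("male", "female", "pup", "object"),
                       amplitude = c(male = 0.15, female = 0, pup = 0, object = 0),
                       response_prob = c(male = 0.9, female = 0.9,
                                         pup = 0.9, object = 0.9),
                       tau_rise = 0.2, tau_off = 12,
                       bleach_amplitude = 0.2, tau_bleach = NULL,
                       noise_sd = 0.3, f0 = 100,
                       n_presentations = 5, presentation_dur = 10,
                       presentation_gap = 40, stimulus_break = 300,
                       stimulus_duration = 600, mean_bout = 3, mean_gap = 15,
                       min_bout = 0.8, attack_prob = 0.3,
                       intro_time = 30, tail = 60,
                       session_length = NULL) {
  paradigm <- match.arg(paradigm)
  stimuli <- match.arg(stimuli, several.ok = TRUE)
  if (fs <= 0) stop("`fs` must be positive")
  if (tau_rise <= 0 || tau_off <= 0) stop("time constants must be positive")
  amplitude <- amplitude[stimuli]
  response_prob <- response_prob[stimuli]
  if (anyNA(amplitude)) stop("`amplitude` must name every stimulus")
  if (anyNA(response_prob) || any(response_prob < 0 | response_prob > 1)) {
    stop("`response_prob` must name every stimulus and lie in [0, 1]")
  }
  cfg <- list(seed = as.integer(seed), fs = fs, paradigm = paradigm,
              stimuli = stimuli, amplitude = amplitude,
              response_prob = response_prob,
              tau_rise = tau_rise, tau_off = tau_off,
              bleach_amplitude = bleach_amplitude, tau_bleach = tau_bleach,
              noise_sd = noise_sd, f0 = f0,
              n_presentations = n_presentations,
              presentation_dur = presentation_dur,
              presentation_gap = presentation_gap,
              stimulus_break = stimulus_break,
              stimulus_duration = stimulus_duration,
              mean_bout = mean_bout, mean_gap = mean_gap, min_bout = min_bout,
              attack_prob = attack_prob, intro_time = intro_time, tail = tail,
              session_length = session_length)
  class(cfg) <- "sim_config"
  cfg
}

#' Foxp2-like and Dbx1-like configuration presets
#'
#' `sim_config_foxp2()`: male-specific tuning with slow offset decay
#' (`tau_off = 12` s). `sim_config_dbx1()`: broad social tuning, strongest to
#' the female, with fast offset decay (`tau_off = 1.2` s). Additional
#' arguments are passed to [sim_config()].
#'
#' @param ... Overrides passed to [sim_config()].
#' @rdname sim_config_presets
#' @export
sim_config_foxp2 <- function(...) {
  args <- list(amplitude = c(male = 0.15, female = 0, pup = 0, object = 0),
               response_prob = c(male = 0.9, female = 0.9, pup = 0.9,
                                 object = 0.9),
               tau_off = 12)
  override <- list(...)
  do.call(sim_config, utils::modifyList(args, override))
}

#' @rdname sim_config_presets
#' @export
sim_config_dbx1 <- function(...) {
  args <- list(amplitude = c(male = 0.10, female = 0.13, pup = 0.10,
                             object = 0.01),
               response_prob = c(male = 0.9, female = 0.9, pup = 0.9,
                                 object = 0.9),
               tau_off = 1.2)
  override <- list(...)
  do.call(sim_config, utils::modifyList(args, override))
}

# Internal: head-fixed presentation schedule. Each stimulus block holds
# n_presentations of presentation_dur seconds separated by presentation_gap,
# blocks separated by stimulus_break (>= 5 min by default).
schedule_head_fixed <- function(cfg) {
  block_len <- cfg$n_presentations * cfg$presentation_dur +
    (cfg$n_presentations - 1L) * cfg$presentation_gap
  rows <- list()
  t0 <- cfg$intro_time
  for (s in cfg$stimuli) {
    on <- t0 + (seq_len(cfg$n_presentations) - 1L) *
      (cfg$presentation_dur + cfg$presentation_gap)
    rows[[s]] <- data.frame(session = "sim", stimulus = s,
                            behavior = "introduction",
                            onset_s = on, offset_s = on + cfg$presentation_dur)
    t0 <- t0 + block_len + cfg$stimulus_break
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Internal: freely-moving bout schedule; draws are taken from the current RNG
# stream. Returns investigation (and, for the male, attack) bouts.
schedule_freely_moving <- function(cfg) {
  rows <- list()
  t0 <- cfg$intro_time
  k <- 1L
  for (s in cfg$stimuli) {
    t_end <- t0 + cfg$stimulus_duration
    t <- t0 + stats::rexp(1L, 1 / cfg$mean_gap)
    while (t < t_end - cfg$min_bout) {
      dur <- cfg$min_bout + stats::rexp(1L, 1 / max(cfg$mean_bout - cfg$min_bout, 0.1))
      off <- min(t + dur, t_end)
      rows[[k]] <- data.frame(session = "sim", stimulus = s,
                              behavior = "investigation",
                              onset_s = t, offset_s = off)
      k <- k + 1L
      t <- off
      if (s == "male" && stats::runif(1L) < cfg$attack_prob) {
        a_on <- off + stats::runif(1L, 0.1, 0.8)
        a_off <- min(a_on + 1 + stats::rexp(1L, 1), t_end)
        if (a_off > a_on + 0.2) {
          rows[[k]] <- data.frame(session = "sim", stimulus = s,
                                  behavior = "attack",
                                  onset_s = a_on, offset_s = a_off)
          k <- k + 1L
          t <- a_off
        }
      }
      t <- t + stats::rexp(1L, 1 / cfg$mean_gap)
    }
    t0 <- t_end + cfg$stimulus_break
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Internal: saturating-rise / exponential-offset transient kernel evaluated
# on the session grid for one bout, added in place.
add_bout_kernel <- function(transient, time, onset, offset, amp, tau_r, tau_off) {
  r_off <- 1 - exp(-(offset - onset) / tau_r)
  t_stop <- offset + tau_off * log(1e4 * max(r_off, 1e-12))
  i <- which(time >= onset & time <= min(t_stop, time[length(time)]))
  if (!length(i)) return(transient)
  tt <- time[i]
  rise <- tt < offset
  v <- numeric(length(tt))
  v[rise] <- 1 - exp(-(tt[rise] - onset) / tau_r)
  v[!rise] <- r_off * exp(-(tt[!rise] - offset) / tau_off)
  transient[i] <- transient[i] + amp * v
  transient
}

#' Simulate a photometry session with known ground truth
#'
#' Builds the stimulus/behavior schedule for the configured paradigm, draws
#' per-bout response flags (Bernoulli with the per-stimulus probability),
#' convolves responding bouts with the rise/decay transient kernel, and
#' assembles the raw trace as
#' `drift(t) * (1 + transient(t)) + noise`, with multiplicative exponential
#' photobleaching drift and i.i.d. Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{trace}{[photometry_trace()] of the raw signal.}
#'     \item{bouts}{[bout_table()] of every presentation/bout.}
#'     \item{truth}{Ground truth: `drift` (raw units), `transient` (exact
#'       latent dF/F), `fz_latent` (whole-trace z-score of the latent dF/F,
#'       an `fz_trace`), `bouts` (schedule with per-bout `responded` flag and
#'       latent threshold-crossing time `crossing_s`, the first time the
#'       bout-normalized latent Fz reaches 1), and the configuration.}
#'   }
#' @export
simulate_photometry_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  sched <- if (cfg$paradigm == "head_fixed") schedule_head_fixed(cfg) else
    schedule_freely_moving(cfg)
  needed <- max(sched$offset_s) + cfg$tail
  session_length <- cfg$session_length
  if (is.null(session_length)) {
    session_length <- needed
  } else if (session_length < needed) {
    stop(sprintf("session_length (%.1f s) does not cover the schedule (%.1f s needed)",
                 session_length, needed))
  }
  tau_bleach <- if (is.null(cfg$tau_bleach)) session_length else cfg$tau_bleach

  n <- floor(session_length * cfg$fs) + 1L
  time <- (seq_len(n) - 1L) / cfg$fs

  # per-bout response draws
  p <- cfg$response_prob[sched$stimulus]
  responded <- stats::runif(nrow(sched)) < p
  amp <- cfg$amplitude[sched$stimulus]
  responded <- responded & amp != 0  # a bout only "responds" if it drives a transient

  transient <- numeric(n)
  for (i in seq_len(nrow(sched))) {
    if (responded[i] && amp[i] != 0) {
      transient <- add_bout_kernel(transient, time, sched$onset_s[i],
                                   sched$offset_s[i], amp[i],
                                   cfg$tau_rise, cfg$tau_off)
    }
  }

  drift <- cfg$f0 * ((1 - cfg$bleach_amplitude) +
                       cfg$bleach_amplitude * exp(-time / tau_bleach))
  f_raw <- drift * (1 + transient) + stats::rnorm(n, 0, cfg$noise_sd)
  trace <- photometry_trace(time, f_raw, cfg$fs)
  bouts <- bout_table(sched)

  # latent Fz: z-score of the exact latent dF/F (the transient itself)
  s_tr <- stats::sd(transient)
  fz_latent <- if (s_tr > 0) (transient - mean(transient)) / s_tr else transient
  fz_latent <- structure(list(time = time, fz = fz_latent, fs = cfg$fs),
                         class = "fz_trace")

  # latent threshold crossings, under the package-wide "signal at time 0"
  # convention (mean of the two samples straddling the bout onset)
  crossing <- rep(NA_real_, nrow(sched))
  for (i in seq_len(nrow(sched))) {
    idx <- which(time >= sched$onset_s[i] - 1e-9 &
                   time < sched$offset_s[i] - 1e-9)
    if (length(idx) < 2L) next
    i0 <- max(findInterval(sched$onset_s[i] + 1e-9, time), 1L)
    f0 <- mean(fz_latent$fz[c(i0, min(i0 + 1L, n))])
    nrm <- fz_latent$fz[idx] - f0
    hit <- which(nrm >= 1)
    if (length(hit)) crossing[i] <- time[idx[hit[1L]]]
  }

  truth <- list(drift = drift, transient = transient, fz_latent = fz_latent,
                bouts = cbind(sched, responded = responded,
                              crossing_s = crossing),
                session_length = session_length, config = cfg)
  list(trace = trace, bouts = bouts, truth = truth)
}

#' Simulate a per-region cell-count table
#'
#' Draws `n_cells` retrogradely labeled cells over regions by a multinomial
#' with the given true fractions, plus a starter-cell tally with a
#' configurable in-target fraction, as a fixture for input-fraction
#' quantification.
#'
#' @param fractions Named numeric vector of true per-region fractions,
#'   summing to 1 within 1e-9.
#' @param n_cells Total number of labeled cells.
#' @param starter_in,starter_out Starter cells inside/outside the target
#'   structure.
#' @param tracer `"rabies"` or `"anterograde"`.
#' @param animal Animal identifier recorded in the table metadata.
#' @param seed Integer seed.
#' @return A list with `table` (a [region_quant_table()] of counts) and
#'   `truth` (the true fractions).
#' @export
simulate_count_table <- function(fractions, n_cells, starter_in = 80,
                                 starter_out = 20, tracer = "rabies",
                                 animal = "sim1", seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1 (within 1e-9)")
  }
  if (is.null(names(fractions))) stop("`fractions` must be named by region")
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1L, n_cells, fractions))
  tab <- region_quant_table(data.frame(region = names(fractions),
                                       count = counts),
                            tracer = tracer, animal = animal,
                            starter_in = starter_in,
                            starter_out = starter_out)
  list(table = tab, truth = list(fractions = fractions, n_cells = n_cells))
}

#' Simulate optogenetically evoked PSC sweep sets
#'
#' Generates, for each pharmacological condition (ACSF, TTX, TTX+4AP), a set
#' of voltage-clamp sweeps: Gaussian baseline noise plus an alpha-shaped
#' postsynaptic current starting exactly `latency_ms` after light onset. The
#' PSC sign follows the holding potential (inward/negative at -70 mV,
#' outward/positive at 0 mV) and its amplitude per condition follows the
#' connection class: monosynaptic responses are abolished by TTX and
#' recovered by TTX+4AP; polysynaptic responses are abolished by TTX and not
#' recovered; `"none"` has no response in any condition.
#'
#' @param latency_ms True synaptic latency from light onset, ms (> 0).
#' @param amplitude_pA Peak PSC amplitude in ACSF, pA (magnitude).
#' @param holding_mV Holding potential, -70 (oEPSC) or 0 (oIPSC).
#' @param connection `"monosynaptic"`, `"polysynaptic"` or `"none"`.
#' @param fs Sampling rate, Hz (default 20000).
#' @param sweep_ms Sweep length, ms.
#' @param light_onset_ms Light pulse onset within the sweep, ms.
#' @param n_sweeps Sweeps per condition (default 10).
#' @param noise_sd_pA Baseline noise SD, pA.
#' @param tau_ms Alpha-function time-to-peak, ms.
#' @param recovery_gain TTX+4AP amplitude relative to ACSF for monosynaptic
#'   connections.
#' @param seed Integer seed.
#' @return A list with `sweeps` (named list of [psc_sweep_set()] per
#'   condition) and `truth` (latency, amplitude, connection class).
#' @export
simulate_psc_sweeps <- function(latency_ms = 4, amplitude_pA = 80,
                                holding_mV = -70,
                                connection = c("monosynaptic",
                                               "polysynaptic", "none"),
                                fs = 20000, sweep_ms = 300,
                                light_onset_ms = 100, n_sweeps = 10,
                                noise_sd_pA = 2, tau_ms = 3,
                                recovery_gain = 0.8, seed = 1L) {
  connection <- match.arg(connection)
  if (latency_ms <= 0) stop("`latency_ms` must be positive")
  if (!holding_mV %in% c(-70, 0)) stop("`holding_mV` must be -70 or 0")
  set.seed(seed)
  gains <- switch(connection,
                  monosynaptic = c(ACSF = 1, TTX = 0, `TTX+4AP` = recovery_gain),
                  polysynaptic = c(ACSF = 1, TTX = 0, `TTX+4AP` = 0),
                  none = c(ACSF = 0, TTX = 0, `TTX+4AP` = 0))
  n <- floor(sweep_ms * fs / 1000) + 1L
  time_ms <- (seq_len(n) - 1L) / fs * 1000
  sgn <- if (holding_mV == -70) -1 else 1
  t_on <- light_onset_ms + latency_ms
  rel <- pmax(time_ms - t_on, 0)
  shape <- (rel / tau_ms) * exp(1 - rel / tau_ms)
  shape[time_ms < t_on] <- 0

  sweeps <- lapply(names(gains), function(cond) {
    amp <- gains[[cond]] * amplitude_pA
    cur <- vapply(seq_len(n_sweeps), function(k) {
      sgn * amp * shape + stats::rnorm(n, 0, noise_sd_pA)
    }, numeric(n))
    psc_sweep_set(time_ms = time_ms, current = cur, fs = fs,
                  light_onset_ms = light_onset_ms, holding_mV = holding_mV,
                  condition = cond)
  })
  names(sweeps) <- names(gains)
  list(sweeps = sweeps,
       truth = list(latency_ms = latency_ms, amplitude_pA = amplitude_pA,
                    connection = connection, gains = gains))
}
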