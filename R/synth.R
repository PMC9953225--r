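# Stage-conditioned synthetic EEG.
#
# Each stage has a spectral profile: relative weights over the canonical EEG
# bands, an overall amplitude, white-noise sd, and (N2 only) a sleep-spindle
# burst rate. Epochs are sums of band-limited random-phase oscillations plus
# noise; stage sequences come from a first-order Markov chain.

#' Run an expression with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Frequency bands used by the generator (Hz)
#' @return Named list of `c(lo, hi)` band edges: delta, theta, alpha, sigma,
#'   beta.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       sigma = c(12, 14), beta = c(13, 30))
}

#' Spectral profile of one sleep stage
#'
#' @param band_weights named numeric vector of nonnegative relative power
#'   weights over the bands of [eeg_bands()]; at least one positive.
#' @param amplitude overall oscillation amplitude scale (microvolt-like units).
#' @param spindle_burst_rate expected number of 12-14 Hz spindle bursts per
#'   30-s epoch (nonzero only for N2 by default).
#' @param noise_sd standard deviation of additive white noise.
#' @return An object of class `"stage_profile"`.
#' @export
stage_profile <- function(band_weights, amplitude = 30,
                          spindle_burst_rate = 0, noise_sd = 5) {
  w <- rep(0, length(eeg_bands()))
  names(w) <- names(eeg_bands())
  if (is.null(names(band_weights)) ||
      !all(names(band_weights) %in% names(w))) {
    stop("band_weights must be named with bands from eeg_bands()")
  }
  w[names(band_weights)] <- as.numeric(band_weights)
  if (any(w < 0) || all(w == 0)) {
    stop("band weights must be nonnegative with at least one positive")
  }
  structure(list(band_weights = w, amplitude = amplitude,
                 spindle_burst_rate = spindle_burst_rate,
                 noise_sd = noise_sd),
            class = "stage_profile")
}

#' Default per-stage spectral profiles
#'
#' Wake is alpha-dominant; N1 theta-dominant at low amplitude; N2 mixed
#' theta/delta with sleep-spindle bursts; N3 delta-dominant at high
#' amplitude; REM mixed theta/beta. These mimic the qualitative
#' stage-dependent spectra of scored sleep EEG without claiming
#' physiological calibration.
#'
#' @return Named list of `stage_profile` objects, one per stage.
#' @export
default_stage_profiles <- function() {
  list(
    W   = stage_profile(c(alpha = 1.0, beta = 0.3, theta = 0.2),
                        amplitude = 30),
    N1  = stage_profile(c(theta = 1.0, alpha = 0.3, beta = 0.2),
                        amplitude = 20),
    N2  = stage_profile(c(theta = 0.8, delta = 0.4, beta = 0.1),
                        amplitude = 40, spindle_burst_rate = 3),
    N3  = stage_profile(c(delta = 1.0, theta = 0.3),
                        amplitude = 75),
    REM = stage_profile(c(theta = 0.8, beta = 0.6, alpha = 0.2),
                        amplitude = 25)
  )
}

#' Markov model of stage transitions at 30-s resolution
#'
#' @param matrix 5x5 row-stochastic matrix (rows/cols in [stage_levels()]
#'   order); each row must sum to 1 within 1e-9.
#' @param initial probability vector of length 5 for the first epoch.
#' @return An object of class `"transition_model"`.
#' @export
transition_model <- function(matrix, initial) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(5L, 5L))) stop("transition matrix must be 5x5")
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-9)) {
    stop("transition matrix must be row-stochastic (rows sum to 1)")
  }
  initial <- as.numeric(initial)
  if (length(initial) != 5L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop("initial distribution must be a length-5 probability vector")
  }
  dimnames(matrix) <- list(stage_levels(), stage_levels())
  structure(list(matrix = matrix, initial = stats::setNames(initial, stage_levels())),
            class = "transition_model")
}

#' Default stage-transition model
#'
#' Strong self-transitions (diagonal 0.85) with plausible off-diagonal
#' structure: W feeds N1, N1 feeds N2, N2 exchanges with N3 and REM, N3
#' returns through N2, REM returns to N2/N1/W. Produces realistic stage runs
#' for 25-epoch training sequences.
#'
#' @return A `transition_model`.
#' @export
default_transition_model <- function() {
  P <- rbind(
    W   = c(0.85, 0.12, 0.02, 0.00, 0.01),
    N1  = c(0.05, 0.85, 0.08, 0.00, 0.02),
    N2  = c(0.01, 0.03, 0.85, 0.06, 0.05),
    N3  = c(0.00, 0.01, 0.13, 0.85, 0.01),
    REM = c(0.03, 0.05, 0.06, 0.01, 0.85)
  )
  transition_model(P, initial = c(1, 0, 0, 0, 0))
}

#' Stationary distribution of a transition model
#' @param tm a `transition_model`.
#' @return Named probability vector of length 5.
#' @export
stationary_distribution <- function(tm) {
  e <- eigen(t(tm$matrix))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), stage_levels())
}

#' Generate one synthetic 30-s EEG epoch for a given stage
#'
#' The signal is a weighted sum of band-limited oscillations (three
#' random-frequency, random-phase sinusoids per active band, with amplitude
#' proportional to the square root of the band's relative power weight),
#' plus optional 13 Hz spindle bursts with Hann-tapered 1-s envelopes, plus
#' white noise. Deterministic given `(stage, fs, profile, seed)`.
#'
#' @param stage stage code.
#' @param fs sampling rate in Hz.
#' @param profile a `stage_profile`; default taken from
#'   [default_stage_profiles()] for `stage`.
#' @param seed integer RNG seed.
#' @param subject_id,epoch_index passed through to the returned record.
#' @param amplitude_scale extra multiplicative amplitude factor (used for
#'   per-subject variation).
#' @return An `epoch_record`.
#' @export
#' @examples
#' e <- generate_epoch("N3", fs = 100, seed = 1)
#' length(e$samples)  # 3000
generate_epoch <- function(stage, fs = 100, profile = NULL, seed = 1,
                           subject_id = "s1", epoch_index = 0L,
                           amplitude_scale = 1) {
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  stage <- match.arg(stage, stage_levels())
  if (is.null(profile)) profile <- default_stage_profiles()[[stage]]
  stopifnot(inherits(profile, "stage_profile"))
  n <- round(fs * 30)
  t <- seq(0, by = 1 / fs, length.out = n)
  bands <- eeg_bands()
  w <- profile$band_weights
  relw <- w / sum(w)
  sig <- with_seed(seed, {
    s <- numeric(n)
    for (b in names(bands)) {
      if (w[b] <= 0) next
      amp <- profile$amplitude * sqrt(relw[b])
      for (k in 1:3) {
        f <- stats::runif(1, bands[[b]][1], bands[[b]][2])
        ph <- stats::runif(1, 0, 2 * pi)
        s <- s + (amp / sqrt(3)) * sin(2 * pi * f * t + ph)
      }
    }
    if (profile$spindle_burst_rate > 0) {
      nb <- stats::rpois(1, profile$spindle_burst_rate)
      if (nb > 0) {
        blen <- round(fs)  # 1-s bursts
        env <- 0.5 * (1 - cos(2 * pi * seq_len(blen) / (blen + 1)))  # Hann
        for (k in seq_len(nb)) {
          start <- sample.int(n - blen, 1)
          f <- stats::runif(1, 12, 14)
          ph <- stats::runif(1, 0, 2 * pi)
          idx <- start:(start + blen - 1L)
          s[idx] <- s[idx] +
            1.2 * profile$amplitude * env * sin(2 * pi * f * t[idx] + ph)
        }
      }
    }
    s + stats::rnorm(n, sd = profile$noise_sd)
  })
  epoch_record(amplitude_scale * sig, fs, stage, subject_id, epoch_index)
}

#' Generate a whole-night synthetic recording
#'
#' Draws a stage sequence from the Markov transition model, then one epoch
#' per stage. Deterministic given the seed.
#'
#' @param n_epochs number of 30-s epochs (>= 1).
#' @param transitions a `transition_model`.
#' @param fs sampling rate in Hz.
#' @param seed integer master seed.
#' @param profiles named list of `stage_profile`s (default
#'   [default_stage_profiles()]).
#' @param subject_id subject identifier.
#' @param amplitude_scale per-subject amplitude factor.
#' @return A list with components `epochs` (an `epoch_set`) and `hypnogram`.
#' @export
generate_recording <- function(n_epochs, transitions = default_transition_model(),
                               fs = 100, seed = 1,
                               profiles = default_stage_profiles(),
                               subject_id = "s1", amplitude_scale = 1) {
  if (n_epochs < 1) stop("n_epochs must be >= 1")
  stopifnot(inherits(transitions, "transition_model"))
  draws <- with_seed(seed, {
    st <- character(n_epochs)
    st[1] <- sample(stage_levels(), 1, prob = transitions$initial)
    if (n_epochs > 1) {
      for (i in 2:n_epochs) {
        st[i] <- sample(stage_levels(), 1,
                        prob = transitions$matrix[st[i - 1], ])
      }
    }
    list(stages = st,
         epoch_seeds = sample.int(.Machine$integer.max - 1L, n_epochs))
  })
  n <- round(fs * 30)
  x <- matrix(0, n_epochs, n)
  for (i in seq_len(n_epochs)) {
    x[i, ] <- generate_epoch(draws$stages[i], fs, profiles[[draws$stages[i]]],
                             seed = draws$epoch_seeds[i],
                             subject_id = subject_id,
                             epoch_index = i - 1L,
                             amplitude_scale = amplitude_scale)$samples
  }
  es <- epoch_set(x, draws$stages, subject_id, seq_len(n_epochs) - 1L, fs)
  list(epochs = es, hypnogram = hypnogram(draws$stages, subject_id))
}

#' Generate a multi-subject synthetic cohort
#'
#' Each subject gets an independent seed derived from the master seed and a
#' subject-specific amplitude factor drawn log-uniformly in `[0.8, 1.25]`,
#' creating the cross-subject variation that subject-wise folds exercise.
#'
#' @param n_subjects number of subjects (>= 2, so subject-wise folds exist).
#' @param n_epochs epochs per subject.
#' @param fs sampling rate in Hz.
#' @param seed integer master seed.
#' @param transitions a `transition_model`.
#' @param profiles named list of `stage_profile`s.
#' @return A pooled `epoch_set` covering all subjects (`subject_id`s
#'   `"s01"`, `"s02"`, ...).
#' @export
generate_cohort <- function(n_subjects, n_epochs, fs = 100, seed = 1,
                            transitions = default_transition_model(),
                            profiles = default_stage_profiles()) {
  if (n_subjects < 2) stop("need at least 2 subjects for cross-validation")
  pars <- with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n_subjects),
         scales = exp(stats::runif(n_subjects, log(0.8), log(1.25))))
  })
  ids <- sprintf("s%02d", seq_len(n_subjects))
  sets <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    sets[[j]] <- generate_recording(n_epochs, transitions, fs,
                                    seed = pars$seeds[j],
                                    profiles = profiles,
                                    subject_id = ids[j],
                                    amplitude_scale = pars$scales[j])$epochs
  }
  epoch_rbind(sets)
}
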