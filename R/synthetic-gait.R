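#' Gait template parameters for the synthetic generator
#'
#' Parameterizes the synthetic walking model: per-cycle timing, the three
#' critical-point amplitudes of the M-shaped stance vGRF curve (first vertical
#' peak VP1, trough TR, second vertical peak VP2), and the stochastic terms.
#'
#' Timing convention: both feet share the cycle period; the contralateral
#' foot's initial contact is offset by `(stance_fraction -
#' double_support_fraction)` of a cycle, so the double support that follows
#' each contralateral initial contact lasts exactly
#' `double_support_fraction` of a cycle.
#'
#' @param cycle_duration gait-cycle period in seconds.
#' @param stance_fraction fraction of the cycle spent in stance, in (0, 1).
#' @param double_support_fraction fraction of the cycle spent in the double
#'   support that follows a contralateral initial contact, in
#'   (0, `stance_fraction`).
#' @param body_weight body weight in newtons.
#' @param peak1_amp,peak2_amp amplitudes (N) of the two vertical peaks.
#' @param trough_amp amplitude (N) of the mid-stance trough.
#' @param timing_jitter_sd SD (seconds) of Gaussian jitter added to each
#'   stance's contact instants.
#' @param amplitude_jitter_sd SD of the relative Gaussian jitter applied to
#'   each stance's amplitudes.
#' @param noise_sd SD of additive white Gaussian noise on the acceleration
#'   channels (channel units). Reference vGRF is never noise-corrupted so
#'   that swing samples stay exactly zero.
#' @param sampling_rate sampling frequency in Hz.
#' @return a `gait_params` list.
#' @export
gait_params <- function(cycle_duration = 1.1,
                        stance_fraction = 0.62,
                        double_support_fraction = 0.10,
                        body_weight = 700,
                        peak1_amp = 770,
                        peak2_amp = 750,
                        trough_amp = 525,
                        timing_jitter_sd = 0,
                        amplitude_jitter_sd = 0,
                        noise_sd = 0,
                        sampling_rate = 128) {
  p <- list(cycle_duration = cycle_duration,
            stance_fraction = stance_fraction,
            double_support_fraction = double_support_fraction,
            body_weight = body_weight,
            peak1_amp = peak1_amp, peak2_amp = peak2_amp,
            trough_amp = trough_amp,
            timing_jitter_sd = timing_jitter_sd,
            amplitude_jitter_sd = amplitude_jitter_sd,
            noise_sd = noise_sd,
            sampling_rate = sampling_rate)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]])) {
      stop_param(paste0("`", nm, "` must be a single finite number."))
    }
  }
  if (!(p$double_support_fraction > 0 &&
        p$double_support_fraction < p$stance_fraction &&
        p$stance_fraction < 1)) {
    stop_param("need 0 < double_support_fraction < stance_fraction < 1.")
  }
  # at least one foot on the ground at all times (walking, no flight phase)
  if (2 * p$stance_fraction - p$double_support_fraction < 1) {
    stop_param("timing implies a flight phase; increase stance_fraction or double_support_fraction.")
  }
  if (!(p$peak1_amp > p$trough_amp && p$peak2_amp > p$trough_amp && p$trough_amp > 0)) {
    stop_param("need peak amplitudes > trough_amp > 0.")
  }
  if (p$timing_jitter_sd < 0 || p$amplitude_jitter_sd < 0 || p$noise_sd < 0) {
    stop_param("jitter and noise SDs must be >= 0.")
  }
  if (p$cycle_duration <= 0 || p$sampling_rate <= 0 || p$body_weight <= 0) {
    stop_param("cycle_duration, sampling_rate and body_weight must be positive.")
  }
  structure(p, class = "gait_params")
}

# M-shaped stance template on normalized stance time tau in [0, 1):
# quarter-sine loading to VP1 at tau = 0.25, raised-cosine dip to TR at 0.5,
# raised-cosine rise to VP2 at 0.75, quarter-cosine unloading to 0.
# Nonzero slope at contact instants keeps threshold crossings sharp.
stance_shape <- function(tau, p1, p2, tr) {
  y <- numeric(length(tau))
  i <- tau >= 0 & tau < 0.25
  y[i] <- p1 * sin(pi / 2 * tau[i] / 0.25)
  i <- tau >= 0.25 & tau < 0.5
  y[i] <- tr + (p1 - tr) * (1 + cos(pi * (tau[i] - 0.25) / 0.25)) / 2
  i <- tau >= 0.5 & tau < 0.75
  y[i] <- tr + (p2 - tr) * (1 - cos(pi * (tau[i] - 0.5) / 0.25)) / 2
  i <- tau >= 0.75 & tau <= 1
  y[i] <- p2 * cos(pi / 2 * (tau[i] - 0.75) / 0.25)
  y
}

# Continuous-time stance intervals for one foot; only stances whose final
# contact lands inside the recording are kept, so true events and
# threshold-detected events agree.
foot_stances <- function(params, n_cycles, offset_s, jit_ic, jit_fc, amp) {
  T <- params$cycle_duration
  ic <- (seq_len(n_cycles) - 1) * T + offset_s + jit_ic
  fc <- ic + params$stance_fraction * T + jit_fc
  tibble(ic_t = ic, fc_t = fc, amp = amp)
}

render_foot <- function(stances, n, rate) {
  grf <- numeric(n)
  ev_ic <- integer(0)
  ev_fc <- integer(0)
  for (s in seq_len(nrow(stances))) {
    ic_t <- stances$ic_t[s]
    fc_t <- stances$fc_t[s]
    k_ic <- as.integer(ceiling(ic_t * rate - 1e-9))
    k_fc <- as.integer(ceiling(fc_t * rate - 1e-9))
    if (k_ic < 0 || k_fc > n - 1) next  # truncated at a recording edge
    ks <- k_ic:(k_fc - 1L)
    tau <- (ks / rate - ic_t) / (fc_t - ic_t)
    grf[ks + 1L] <- stances$amp[s] *
      stance_shape(tau, stances$p1[s], stances$p2[s], stances$tr[s])
    ev_ic <- c(ev_ic, k_ic)
    ev_fc <- c(ev_fc, k_fc)
  }
  list(grf = pmax(grf, 0), ic = ev_ic, fc = ev_fc)
}

#' Generate bilateral synthetic vGRF profiles
#'
#' Builds seeded left/right vertical ground reaction force traces with
#' M-shaped stance profiles (two vertical peaks bracketing a trough), feet
#' alternating with the configured double-support overlap, and the true
#' initial-contact (IC) / final-contact (FC) sample indices.
#'
#' @param params a [gait_params()] object.
#' @param n_cycles number of gait cycles (>= 1).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `grf` (tibble `k`, `grf_left`, `grf_right`), `events`
#'   (tibble `foot`, `event`, `k`) and `sampling_rate`.
#' @export
generate_vgrf_profiles <- function(params, n_cycles, seed = 1) {
  if (!inherits(params, "gait_params")) params <- do.call(gait_params, params)
  if (n_cycles < 1) stop_param("`n_cycles` must be >= 1.")
  rate <- params$sampling_rate
  T <- params$cycle_duration
  n <- as.integer(round(n_cycles * T * rate))
  offset <- (params$stance_fraction - params$double_support_fraction) * T

  with_seed(seed, {
    draws <- lapply(c(left = 0, right = offset), function(off) {
      jit_ic <- rnorm(n_cycles, 0, params$timing_jitter_sd)
      jit_fc <- rnorm(n_cycles, 0, params$timing_jitter_sd)
      amp <- pmax(1 + rnorm(n_cycles, 0, params$amplitude_jitter_sd), 0.05)
      st <- foot_stances(params, n_cycles, off, jit_ic, jit_fc, amp)
      st$p1 <- params$peak1_amp
      st$p2 <- params$peak2_amp
      st$tr <- params$trough_amp
      st
    })
    feet <- lapply(draws, render_foot, n = n, rate = rate)
    events <- dplyr::bind_rows(lapply(names(feet), function(f) {
      dplyr::arrange(tibble(
        foot = f,
        event = rep(c("IC", "FC"), c(length(feet[[f]]$ic), length(feet[[f]]$fc))),
        k = c(feet[[f]]$ic, feet[[f]]$fc)), .data$k)
    }))
    list(grf = tibble(k = 0:(n - 1L),
                      grf_left = feet$left$grf,
                      grf_right = feet$right$grf),
         events = dplyr::arrange(events, .data$k, .data$foot),
         sampling_rate = rate)
  })
}

#' Generate a biomechanically shaped synthetic recording
#'
#' Produces a full recording whose acceleration channels are dynamically
#' coupled to the generated vGRF, so that the inverse map (acceleration to
#' per-foot force) lies inside the degree-2 nonlinear moving-average model
#' class over short lags:
#'
#' * `ax` is the total-force fluctuation about body weight passed through a
#'   fixed causal 3-tap exponential kernel (`1, rho, rho^2` with `rho = 0.4`),
#'   whose inverse decays geometrically and is negligible beyond lag 18;
#' * `az` carries a gravity offset (9.81) plus a small stride harmonic, so its
#'   left/right decomposed components approximately encode the membership
#'   weight itself;
#' * `ay` is a stride-frequency harmonic.
#'
#' White Gaussian noise of SD `noise_sd` is added to each acceleration
#' channel. Reference vGRF channels are noise-free.
#'
#' @inheritParams generate_vgrf_profiles
#' @return a [grf_recording()] with attribute `true_events`.
#' @export
generate_biomech_recording <- function(params, n_cycles, seed = 1) {
  if (!inherits(params, "gait_params")) params <- do.call(gait_params, params)
  prof <- generate_vgrf_profiles(params, n_cycles, seed = seed)
  n <- nrow(prof$grf)
  rate <- params$sampling_rate
  cyc <- params$cycle_duration * rate
  k <- prof$grf$k

  rho <- 0.4
  r <- (prof$grf$grf_left + prof$grf$grf_right - params$body_weight) /
    params$body_weight
  lag1 <- c(0, r[-n])
  lag2 <- c(0, 0, r[-c(n - 1, n)])
  ax <- r + rho * lag1 + rho^2 * lag2
  ay <- 0.25 * sin(2 * pi * k / cyc)
  az <- 9.81 + 0.10 * sin(4 * pi * k / cyc)

  noise <- with_seed(seed + 104729L, {
    matrix(rnorm(3L * n, 0, params$noise_sd), ncol = 3)
  })
  rec <- grf_recording(
    tibble(k = k,
           ax = ax + noise[, 1], ay = ay + noise[, 2], az = az + noise[, 3],
           grf_left = prof$grf$grf_left, grf_right = prof$grf$grf_right),
    sampling_rate = rate)
  attr(rec, "true_events") <- prof$events
  rec
}

#' Specify an oracle nonlinear moving-average model
#'
#' An oracle model is a known polynomial map from lagged decomposed
#' acceleration channels to vGRF, used to generate data for exact
#' structure/parameter recovery tests. Each term is a monomial of total
#' degree at most 2 built with [oracle_term()].
#'
#' @param ... [oracle_term()] monomials.
#' @param max_lag maximum lag; defaults to the largest lag used.
#' @return an `oracle_spec` object (tibble of terms plus `max_lag`).
#' @export
oracle_spec <- function(..., max_lag = NULL) {
  terms <- dplyr::bind_rows(list(...))
  if (nrow(terms) > 0) {
    deg <- terms$pow1 + dplyr::coalesce(terms$pow2, 0)
    if (any(deg > 2)) stop_param("oracle monomials must have total degree <= 2.")
    lag_used <- max(c(terms$lag1, terms$lag2), na.rm = TRUE)
  } else {
    lag_used <- 0
  }
  max_lag <- max_lag %||% lag_used
  if (nrow(terms) > 0 && lag_used > max_lag) {
    stop_param("a term uses a lag larger than `max_lag`.")
  }
  structure(list(terms = terms, max_lag = as.integer(max_lag)),
            class = "oracle_spec")
}

#' @rdname oracle_spec
#' @param coefficient real coefficient of the monomial.
#' @param channel,lag,power first factor: decomposed-channel name (e.g.
#'   `"ax_left"`), lag in samples, integer power.
#' @param channel2,lag2,power2 optional second factor.
#' @export
oracle_term <- function(coefficient, channel, lag, power = 1,
                        channel2 = NA_character_, lag2 = NA_integer_,
                        power2 = 1L) {
  if (any(c(lag, lag2) < 0, na.rm = TRUE)) stop_param("lags must be >= 0.")
  t <- tibble(chan1 = channel, lag1 = as.integer(lag), pow1 = as.integer(power),
              chan2 = channel2,
              lag2 = as.integer(lag2),
              pow2 = ifelse(is.na(channel2), NA_integer_, as.integer(power2)),
              coefficient = coefficient)
  canonicalize_terms(t)
}

decomposed_channels <- function() {
  c("ax_left", "ax_right", "ay_left", "ay_right", "az_left", "az_right")
}

#' Generate oracle-mode data
#'
#' Draws six decomposed input channels directly — seeded white noise gated by
#' alternating stance-like windows with double-support overlap — and computes
#' left/right outputs exactly by evaluating the oracle model (the right-foot
#' output uses the spec with left/right channel roles mirrored). Outputs at
#' `k < max_lag` are 0 by convention; recovery tests use `k >= max_lag`.
#'
#' @param spec an [oracle_spec()].
#' @param n_samples number of samples; must exceed `max_lag + 10`.
#' @param seed integer seed.
#' @return list with `signals` (tibble of the six decomposed channels plus
#'   `k`), `grf_left`, `grf_right`, and `max_lag`.
#' @export
generate_oracle_recording <- function(spec, n_samples, seed = 1) {
  stopifnot(inherits(spec, "oracle_spec"))
  if (n_samples <= spec$max_lag + 10) {
    stop_param("`n_samples` must exceed max_lag + 10.")
  }
  n <- as.integer(n_samples)
  k <- 0:(n - 1L)
  period <- 64L
  stance_len <- 40L
  gate_left <- as.numeric((k %% period) < stance_len)
  gate_right <- as.numeric(((k + period / 2L) %% period) < stance_len)
  sig <- with_seed(seed, {
    cols <- lapply(decomposed_channels(), function(ch) {
      g <- if (grepl("_left$", ch)) gate_left else gate_right
      rnorm(n) * g
    })
    setNames(cols, decomposed_channels())
  })
  signals <- as_tibble(c(list(k = k), sig))

  eval_out <- function(terms) {
    y <- numeric(n)
    if (nrow(terms) > 0 && n > spec$max_lag) {
      tv <- eval_term_matrix(terms, signals, spec$max_lag)
      y[(spec$max_lag + 1L):n] <- as.vector(tv %*% terms$coefficient)
    }
    y
  }
  mirror <- function(terms) {
    if (nrow(terms) == 0) return(terms)
    sw <- function(ch) {
      out <- ch
      out[grepl("_left$", ch)] <- sub("_left$", "_right", ch[grepl("_left$", ch)])
      out[grepl("_right$", ch)] <- sub("_right$", "_left", ch[grepl("_right$", ch)])
      out
    }
    terms$chan1 <- sw(terms$chan1)
    terms$chan2 <- ifelse(is.na(terms$chan2), terms$chan2, sw(terms$chan2))
    canonicalize_terms(terms)
  }
  list(signals = signals,
       grf_left = eval_out(spec$terms),
       grf_right = eval_out(mirror(spec$terms)),
       max_lag = spec$max_lag)
}
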