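#' Detect gait events from reference vGRF with a force threshold
#'
#' Initial contact (IC) is the first sample of each maximal run with force at
#' or above `threshold`; final contact (FC) is the first sample after the run
#' with force below it (stance is the half-open interval `[IC, FC)`). Runs
#' and gaps shorter than the `min_phase` guard are treated as threshold
#' chatter: sub-guard gaps are bridged, then sub-guard stance runs dropped. A
#' trailing stance that never returns below threshold has no FC and is
#' discarded.
#'
#' @param data data frame with nonnegative `grf_left` and `grf_right` columns
#'   (newtons), e.g. a [grf_recording()].
#' @param threshold detection threshold in newtons (default 10).
#' @param min_phase minimum stance/swing duration in seconds (debounce guard).
#' @param sampling_rate Hz; defaults to the recording's attribute.
#' @return tibble of events: `foot`, `event` (`IC`/`FC`), `k` (0-based).
#' @export
detect_gait_events <- function(data, threshold = 10, min_phase = 0.1,
                               sampling_rate = NULL) {
  if (!is.numeric(threshold) || threshold < 0) {
    stop_param("`threshold` must be a nonnegative force in newtons.")
  }
  if (!all(c("grf_left", "grf_right") %in% names(data))) {
    stop_structure("`data` must contain grf_left and grf_right columns.")
  }
  rate <- sampling_rate %||% attr(data, "sampling_rate") %||% 128
  min_run <- max(1L, as.integer(round(min_phase * rate)))

  one_foot <- function(grf, foot) {
    if (any(grf < 0)) stop_domain("vGRF must be nonnegative.")
    above <- grf >= threshold
    above <- debounce_runs(above, min_run)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ic <- starts[r$values]
    fc <- ends[r$values] + 1L
    keep <- fc <= length(grf)  # incomplete trailing stance has no FC
    ic <- ic[keep]; fc <- fc[keep]
    if (length(ic) == 0) return(tibble(foot = character(), event = character(),
                                       k = integer()))
    tibble(foot = foot,
           event = rep(c("IC", "FC"), each = length(ic)),
           k = as.integer(c(ic, fc) - 1L))  # to 0-based
  }
  ev <- dplyr::bind_rows(one_foot(data$grf_left, "left"),
                         one_foot(data$grf_right, "right"))
  dplyr::arrange(ev, .data$k, .data$foot, dplyr::desc(.data$event))
}

# Bridge sub-guard swing gaps between stances, then drop sub-guard stances.
debounce_runs <- function(above, min_run) {
  if (min_run <= 1L) return(above)
  r <- rle(above)
  short_gap <- !r$values & r$lengths < min_run
  short_gap[c(1, length(r$lengths))] <- FALSE  # recording edges are genuine
  r$values[short_gap] <- TRUE
  r <- rle(inverse.rle(r))
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

validate_events <- function(events) {
  for (f in unique(events$foot)) {
    ev <- dplyr::arrange(dplyr::filter(events, .data$foot == f), .data$k)
    if (nrow(ev) == 0) next
    if (any(diff(ev$k) <= 0)) stop_structure("event indices must be strictly increasing per foot.")
    expected <- rep(c("IC", "FC"), length.out = nrow(ev))
    if (!all(ev$event == expected)) {
      stop_structure("events must alternate IC, FC, ... per foot, starting with IC.")
    }
  }
  invisible(events)
}

# Per-foot stance intervals as half-open [ic, fc) 0-based pairs.
stance_intervals <- function(events, foot) {
  ev <- dplyr::arrange(dplyr::filter(events, .data$foot == !!foot), .data$k)
  ic <- ev$k[ev$event == "IC"]
  fc <- ev$k[ev$event == "FC"]
  n_pairs <- min(length(ic), length(fc))
  tibble(ic = ic[seq_len(n_pairs)], fc = fc[seq_len(n_pairs)])
}

stance_mask <- function(events, foot, n_samples) {
  m <- logical(n_samples)
  iv <- stance_intervals(events, foot)
  for (i in seq_len(nrow(iv))) {
    lo <- max(iv$ic[i], 0L); hi <- min(iv$fc[i] - 1L, n_samples - 1L)
    if (hi >= lo) m[(lo:hi) + 1L] <- TRUE
  }
  m
}

#' Exact membership functions from bilateral reference vGRF
#'
#' The left membership weight is the left share of total vertical force,
#' `grf_left / (grf_left + grf_right)`, and the right weight its complement.
#' Where both forces are zero (both feet unloaded) the membership is
#' undefined and filled by carrying the last defined value forward (0.5
#' before any defined sample).
#'
#' @param data data frame with nonnegative `grf_left`, `grf_right` columns.
#' @return tibble `k`, `w_left`, `w_right` with `w_left + w_right = 1`.
#' @export
exact_membership <- function(data) {
  gl <- data$grf_left; gr <- data$grf_right
  if (is.null(gl) || is.null(gr)) {
    stop_structure("`data` must contain grf_left and grf_right columns.")
  }
  if (any(gl < 0) || any(gr < 0)) stop_domain("vGRF must be nonnegative.")
  tot <- gl + gr
  w <- ifelse(tot > 0, gl / tot, NA_real_)
  w <- carry_fill(w, lead_value = 0.5)
  tibble(k = data[["k"]] %||% (seq_along(gl) - 1L), w_left = w, w_right = 1 - w)
}

carry_fill <- function(x, lead_value) {
  if (all(is.na(x))) return(rep(lead_value, length(x)))
  filled <- !is.na(x)
  idx <- cumsum(filled)
  out <- c(lead_value, x[filled])[idx + 1L]
  out
}

#' Event-based approximate membership functions
#'
#' Approximates the exact force-share membership from gait events alone: the
#' weight is 1 in a foot's single-support phase, 0 throughout its swing, and
#' ramps linearly across each double support — from 1 at the contralateral-IC
#' sample down to 0 at the last double-support sample (the final-contact
#' instant under the half-open stance convention), and symmetrically upward
#' after the foot's own IC. The pair sums to 1 at every sample.
#'
#' @param events gait-events tibble (`foot`, `event`, `k`), alternating
#'   IC/FC per foot.
#' @param n_samples length of the membership sequences.
#' @return tibble `k`, `w_left`, `w_right`.
#' @export
event_membership <- function(events, n_samples) {
  validate_events(events)
  ls <- stance_mask(events, "left", n_samples)
  rs <- stance_mask(events, "right", n_samples)
  covered <- which(ls | rs)
  if (length(covered) == 0) stop_structure("no stance samples covered by events.")
  flight <- !ls & !rs
  interior <- seq_len(n_samples) > min(covered) & seq_len(n_samples) < max(covered)
  if (any(flight & interior)) {
    abort("both feet airborne between stances: walking (no flight phase) is assumed.",
          class = "grfproxy_error_unsupported_input")
  }

  w <- rep(NA_real_, n_samples)
  w[ls & !rs] <- 1
  w[!ls & rs] <- 0
  both <- ls & rs
  r <- rle(both)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  left_ic <- stance_intervals(events, "left")$ic
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]; len <- e - s + 1L
    # a double support opening with the left foot's own IC ramps 0 -> 1;
    # one opening with the contralateral (right) IC ramps 1 -> 0
    rising <- (s - 1L) %in% left_ic
    ramp <- if (len == 1L) {
      if (rising) 1 else 0
    } else if (rising) {
      (seq_len(len) - 1) / (len - 1)
    } else {
      1 - (seq_len(len) - 1) / (len - 1)
    }
    w[s:e] <- ramp
  }
  w <- carry_fill(w, lead_value = w[covered[1]])
  tibble(k = 0:(n_samples - 1L), w_left = w, w_right = 1 - w)
}

#' Decompose acceleration into left- and right-foot components
#'
#' Point-wise multiplication of each acceleration axis by the membership
#' pair, yielding the six input channels of the proxy model. The components
#' reconstruct the original signal exactly: `ax_left + ax_right = ax`, and
#' likewise per axis.
#'
#' @param data data frame with `ax`, `ay`, `az` (e.g. a [grf_recording()]).
#' @param membership membership tibble from [exact_membership()] or
#'   [event_membership()], same length as `data`.
#' @return tibble `k`, `ax_left`, `ax_right`, ..., `az_right`.
#' @export
decompose_acceleration <- function(data, membership) {
  if (nrow(data) != nrow(membership)) {
    stop_structure("`data` and `membership` must have the same number of samples.")
  }
  wl <- membership$w_left; wr <- membership$w_right
  out <- tibble(k = data[["k"]] %||% (seq_len(nrow(data)) - 1L),
                ax_left = data$ax * wl, ax_right = data$ax * wr,
                ay_left = data$ay * wl, ay_right = data$ay * wr,
                az_left = data$az * wl, az_right = data$az * wr)
  attr(out, "sampling_rate") <- attr(data, "sampling_rate")
  out
}

#' Segment a recording into gait cycles
#'
#' A gait cycle runs from one initial contact of the chosen foot to the next
#' (half-open `[IC_i, IC_(i+1))`).
#'
#' @param events gait-events tibble.
#' @param foot `"left"` or `"right"`.
#' @return tibble `cycle`, `start`, `end` (0-based, half-open); empty when
#'   the foot has fewer than two ICs.
#' @export
segment_cycles <- function(events, foot = c("left", "right")) {
  foot <- match.arg(foot)
  ic <- sort(dplyr::filter(events, .data$foot == !!foot, .data$event == "IC")$k)
  if (length(ic) < 2) {
    return(tibble(cycle = integer(), start = integer(), end = integer()))
  }
  tibble(cycle = seq_len(length(ic) - 1L),
         start = as.integer(ic[-length(ic)]),
         end = as.integer(ic[-1]))
}

#' Extract the critical points of one stance vGRF cycle
#'
#' Scans a single gait cycle's vGRF for the two vertical peaks and the
#' intermediate trough of the M-shaped stance curve: VP1 is the first local
#' maximum, VP2 the last, TR the minimum between them. Ties break toward the
#' earlier index.
#'
#' @param cycle_grf numeric vector, one cycle of nonnegative vGRF.
#' @return one-row tibble `vp1_value`, `vp1_index`, `tr_value`, `tr_index`,
#'   `vp2_value`, `vp2_index` (indices 0-based within the cycle).
#' @export
extract_critical_points <- function(cycle_grf) {
  s <- as.numeric(cycle_grf)
  n <- length(s)
  if (n < 3) stop_domain("cycle too short for critical-point extraction.")
  i <- 2:(n - 1)
  is_max <- s[i] >= s[i - 1] & s[i] >= s[i + 1] &
    (s[i] > s[i - 1] | s[i] > s[i + 1])
  maxima <- i[is_max]
  if (length(maxima) < 2) {
    found <- if (length(maxima) == 1) {
      list(value = s[maxima], index = maxima - 1L)
    } else {
      list(value = max(s), index = which.max(s) - 1L)
    }
    abort("stance has fewer than two local maxima (degenerate M-shape).",
          class = "grfproxy_error_degenerate_shape", extremum = found)
  }
  vp1 <- maxima[1]; vp2 <- maxima[length(maxima)]
  between <- vp1:vp2
  tr <- between[which.min(s[between])]
  tibble(vp1_value = s[vp1], vp1_index = vp1 - 1L,
         tr_value = s[tr], tr_index = tr - 1L,
         vp2_value = s[vp2], vp2_index = vp2 - 1L)
}

#' Gait-phase masks
#'
#' Boolean masks per sample for each foot's stance and swing, the
#' single-support phases (one foot in stance while the other swings) and
#' double support (both feet in stance). Single and double support partition
#' total stance time.
#'
#' @param events gait-events tibble.
#' @param n_samples number of samples to cover.
#' @return tibble `k`, `left_stance`, `right_stance`, `left_single`,
#'   `right_single`, `double_support`, `left_swing`, `right_swing`.
#' @export
phase_masks <- function(events, n_samples) {
  validate_events(events)
  ls <- stance_mask(events, "left", n_samples)
  rs <- stance_mask(events, "right", n_samples)
  tibble(k = 0:(n_samples - 1L),
         left_stance = ls, right_stance = rs,
         left_single = ls & !rs, right_single = rs & !ls,
         double_support = ls & rs,
         left_swing = !ls, right_swing = !rs)
}
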