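#' Configuration of the proxy-model pipeline
#'
#' Collects the tunables of [fit_proxy()]: the decomposed channel set, the
#' dictionary geometry (lags `0..max_lag`, polynomial degree, constant
#' term), the selection stopping rule, the number of iterative-OFR restart
#' sweeps, and the gait-event detection settings.
#'
#' @param channels input channel names used by the dictionary.
#' @param max_lag maximum lag in samples (default 18).
#' @param degree polynomial degree, 1 or 2.
#' @param include_constant include the constant dictionary term?
#' @param stop a [stopping_rule()]; default a fixed 64-term model.
#' @param iofr_iterations restart sweeps of [iofr_select()]; 0 runs plain
#'   greedy OFR.
#' @param event_threshold gait-event force threshold in newtons.
#' @param min_phase event-detection debounce guard in seconds.
#' @param rrmse_scope peak-to-peak normalization of per-cycle relative
#'   errors: `"cycle"` uses each cycle's own range, `"global"` the whole
#'   evaluation segment's.
#' @return a `proxy_config` object.
#' @export
proxy_config <- function(channels = decomposed_channels(), max_lag = 18,
                         degree = 2, include_constant = TRUE,
                         stop = stopping_rule("fixed_terms", n_terms = 64),
                         iofr_iterations = 1, event_threshold = 10,
                         min_phase = 0.1,
                         rrmse_scope = c("cycle", "global")) {
  structure(list(channels = channels, max_lag = as.integer(max_lag),
                 degree = as.integer(degree),
                 include_constant = include_constant, stop = stop,
                 iofr_iterations = as.integer(iofr_iterations),
                 event_threshold = event_threshold, min_phase = min_phase,
                 rrmse_scope = match.arg(rrmse_scope)),
            class = "proxy_config")
}

#' Split a recording into training and test halves
#'
#' Contiguous first half for model identification, second half for
#' validation, with the split aligned to the gait-cycle boundary (an initial
#' contact of `foot`) nearest the midpoint so no cycle spans the boundary.
#'
#' @param data a [grf_recording()] with reference vGRF.
#' @param events optional gait events; detected from the reference vGRF when
#'   absent.
#' @param foot foot whose initial contacts define cycle boundaries.
#' @param ... passed to [detect_gait_events()].
#' @return list with elements `train` and `test` (both `grf_recording`s).
#' @export
split_half <- function(data, events = NULL, foot = "left", ...) {
  n <- nrow(data)
  events <- events %||% detect_gait_events(data, ...)
  ic <- sort(dplyr::filter(events, .data$foot == !!foot,
                           .data$event == "IC")$k)
  ic <- ic[ic > 0 & ic < n - 1]
  if (length(ic) < 1) {
    stop_data("recording too short to split: no interior cycle boundary found.")
  }
  b <- ic[which.min(abs(ic - n / 2))]
  rate <- sampling_rate(data)
  list(train = grf_recording(data[seq_len(b), , drop = FALSE], rate),
       test = grf_recording(data[(b + 1):n, , drop = FALSE], rate))
}

#' Fit left- and right-foot proxy models
#'
#' Runs the full identification pipeline on a training recording with
#' reference vGRF: gait-event detection (10 N threshold by default),
#' event-based membership construction, decomposition of the three
#' acceleration axes into six per-foot channels, candidate-dictionary
#' evaluation (degree 2, lags 0..18 by default), and iterative orthogonal
#' forward regression once per foot against the same dictionary.
#'
#' @param data training [grf_recording()]; must contain `grf_left` and
#'   `grf_right`.
#' @param config a [proxy_config()].
#' @param events optional externally supplied gait events.
#' @return a `proxy_fit`: NMA models `left` and `right`, selection traces
#'   `ofr_left`/`ofr_right`, the dictionary, events and config.
#' @export
fit_proxy <- function(data, config = proxy_config(), events = NULL) {
  if (!has_reference(data)) {
    stop_structure("training requires reference vGRF columns grf_left and grf_right.")
  }
  n <- nrow(data)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", what, "] ", conditionMessage(e)),
            class = "grfproxy_error_stage", parent = e)
    })
  }
  events <- events %||% stage("detect_gait_events",
    detect_gait_events(data, threshold = config$event_threshold,
                       min_phase = config$min_phase))
  membership <- stage("event_membership", event_membership(events, n))
  dec <- stage("decompose_acceleration", decompose_acceleration(data, membership))
  dict <- build_dictionary(config$channels, config$max_lag, config$degree,
                           config$include_constant)
  X <- stage("evaluate_dictionary", evaluate_dictionary(dict, dec))
  L <- dict$max_lag
  fit_one <- function(target, foot) {
    y <- target[(L + 1):n]
    ofr <- if (config$iofr_iterations > 0) {
      iofr_select(X, y, config$stop, max_iterations = config$iofr_iterations)
    } else {
      ofr_select(X, y, config$stop)
    }
    list(ofr = ofr,
         model = ofr_to_nma(ofr, dict,
                            metadata = list(foot = foot,
                                            sampling_rate = sampling_rate(data),
                                            n_train = n)))
  }
  left <- stage("ofr_select(left)", fit_one(data$grf_left, "left"))
  right <- stage("ofr_select(right)", fit_one(data$grf_right, "right"))
  structure(list(left = left$model, right = right$model,
                 ofr_left = left$ofr, ofr_right = right$ofr,
                 dictionary = dict, events = events, config = config,
                 sampling_rate = sampling_rate(data), n_train = n),
            class = "proxy_fit")
}

#' @export
print.proxy_fit <- function(x, ...) {
  cat(sprintf("# proxy fit: %d-term left / %d-term right NMA models (max lag %d, degree %d)\n",
              nrow(x$left$terms), nrow(x$right$terms),
              x$dictionary$max_lag, x$dictionary$max_degree))
  cat(sprintf("#   sum ERR: left %.4f, right %.4f\n",
              x$ofr_left$sum_err, x$ofr_right$sum_err))
  invisible(x)
}

#' Predict bilateral vGRF on a new recording
#'
#' Decomposes the new recording's acceleration with event-based membership
#' (events taken from its reference vGRF when present, mirroring
#' insole-derived events; otherwise they must be supplied) and evaluates the
#' fitted left/right NMA models. Predictions use inputs only; the reference
#' columns never enter the evaluation.
#'
#' @param object a [fit_proxy()] result.
#' @param data a [grf_recording()].
#' @param events optional externally supplied gait events.
#' @param ... unused.
#' @return tibble `k`, `grf_left`, `grf_right` (first `max_lag` samples
#'   `NA`).
#' @export
predict.proxy_fit <- function(object, data, events = NULL, ...) {
  if (is.null(events)) {
    if (!has_reference(data)) {
      stop_structure("supply `events` to predict on a recording without reference vGRF.")
    }
    events <- detect_gait_events(data,
                                 threshold = object$config$event_threshold,
                                 min_phase = object$config$min_phase)
  }
  membership <- event_membership(events, nrow(data))
  dec <- decompose_acceleration(data, membership)
  tibble(k = data$k,
         grf_left = predict_nma(object$left, dec),
         grf_right = predict_nma(object$right, dec))
}

#' Root mean squared error
#'
#' `sqrt(mean((y - y_hat)^2))`; `NA` pairs (e.g. the undefined first
#' `max_lag` predictions) are dropped.
#'
#' @param y,y_hat equal-length numeric vectors.
#' @return RMSE in the units of `y`.
#' @export
compute_rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop_structure("`y` and `y_hat` lengths differ.")
  ok <- !is.na(y) & !is.na(y_hat)
  if (!any(ok)) stop_domain("no complete pairs to compare.")
  sqrt(mean((y[ok] - y_hat[ok])^2))
}

#' Relative RMSE in percent
#'
#' RMSE normalized by the mean of the two signals' peak-to-peak amplitudes
#' (computed over the samples supplied), in percent.
#'
#' @inheritParams compute_rmse
#' @return rRMSE in percent.
#' @export
compute_rrmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop_structure("`y` and `y_hat` lengths differ.")
  ok <- !is.na(y) & !is.na(y_hat)
  if (!any(ok)) stop_domain("no complete pairs to compare.")
  denom <- (diff(range(y[ok])) + diff(range(y_hat[ok]))) / 2
  if (denom <= 0) stop_domain("degenerate signals: zero peak-to-peak amplitude.")
  100 * compute_rmse(y, y_hat) / denom
}

cp_or_null <- function(x) {
  tryCatch(extract_critical_points(x),
           grfproxy_error_degenerate_shape = function(e) NULL,
           grfproxy_error_domain = function(e) NULL)
}

#' Per-cycle prediction-error report
#'
#' Compares predicted and reference vGRF of one foot cycle by cycle: RMSE
#' and relative RMSE for the full cycle, the foot's single-support samples
#' and the double-support samples, plus the three stance critical points
#' (VP1, TR, VP2) extracted independently from the reference and predicted
#' curves of each cycle. Relative errors are normalized by the mean
#' peak-to-peak amplitude (per cycle by default, see
#' [proxy_config()]`$rrmse_scope`); critical-point errors use the same
#' denominator. Aggregates are mean ± SD over cycles, plus the
#' cross-correlation coefficient `rho` over the whole segment. Cycles whose
#' reference curve lacks an M-shape are excluded and counted; a degenerate
#' predicted curve falls back to the predicted value at the reference
#' critical index.
#'
#' @param reference,predicted per-foot vGRF vectors of equal length
#'   (predicted may be `NA` over the first `max_lag` samples).
#' @param events gait events covering the segment.
#' @param foot which foot the series describe.
#' @param rrmse_scope `"cycle"` or `"global"` peak-to-peak normalization.
#' @return an `error_report`: per-cycle tibble `cycles`, aggregate tibble
#'   `summary` (phase by mean/SD of RMSE and rRMSE), `rho`, `n_cycles`,
#'   `n_degenerate`.
#' @export
cycle_error_report <- function(reference, predicted, events,
                               foot = c("left", "right"),
                               rrmse_scope = c("cycle", "global")) {
  foot <- match.arg(foot)
  rrmse_scope <- match.arg(rrmse_scope)
  if (length(reference) != length(predicted)) {
    stop_structure("`reference` and `predicted` lengths differ.")
  }
  n <- length(reference)
  cyc <- segment_cycles(events, foot)
  if (nrow(cyc) == 0) stop_data("need at least two initial contacts to form cycles.")
  masks <- phase_masks(events, n)
  single <- if (foot == "left") masks$left_single else masks$right_single
  dbl <- masks$double_support
  ok <- !is.na(predicted)
  # analysis is per gait cycle: samples outside the segmented cycles (e.g.
  # transitory stretches at the recording edges) never enter the metrics
  covered <- logical(n)
  for (i in seq_len(nrow(cyc))) {
    lo <- max(cyc$start[i], 0L); hi <- min(cyc$end[i] - 1L, n - 1L)
    if (hi >= lo) covered[(lo:hi) + 1L] <- TRUE
  }
  ok <- ok & covered
  if (!any(ok)) stop_data("no valid predictions inside the segmented cycles.")
  global_denom <- (diff(range(reference[ok])) + diff(range(predicted[ok]))) / 2

  rows <- list()
  n_degenerate <- 0L
  for (i in seq_len(nrow(cyc))) {
    idx <- (cyc$start[i]:(cyc$end[i] - 1L)) + 1L
    idx <- idx[idx >= 1 & idx <= n]
    idx <- idx[ok[idx]]
    if (length(idx) < 3) next
    ref <- reference[idx]; prd <- predicted[idx]
    denom <- if (rrmse_scope == "cycle") {
      (diff(range(ref)) + diff(range(prd))) / 2
    } else {
      global_denom
    }
    if (denom <= 0) { n_degenerate <- n_degenerate + 1L; next }
    # critical points live in the loaded part of the cycle: restrict both
    # curves to the reference stance so swing-phase prediction ripple cannot
    # pose as a vertical peak
    stance_i <- which(ref > 0.02 * max(ref))
    if (length(stance_i) < 3) { n_degenerate <- n_degenerate + 1L; next }
    stance_i <- min(stance_i):max(stance_i)
    off <- stance_i[1] - 1L
    ref_cp <- cp_or_null(ref[stance_i])
    if (is.null(ref_cp)) { n_degenerate <- n_degenerate + 1L; next }
    prd_cp <- cp_or_null(prd[stance_i])
    vp1_p <- if (is.null(prd_cp)) prd[ref_cp$vp1_index + off + 1L] else prd_cp$vp1_value
    vp2_p <- if (is.null(prd_cp)) prd[ref_cp$vp2_index + off + 1L] else prd_cp$vp2_value
    tr_p <- if (is.null(prd_cp)) prd[ref_cp$tr_index + off + 1L] else prd_cp$tr_value
    if (is.null(prd_cp)) n_degenerate <- n_degenerate + 1L

    sub_err <- function(mask) {
      j <- idx[mask[idx]]
      if (length(j) == 0) return(c(NA_real_, NA_real_))
      r <- compute_rmse(reference[j], predicted[j])
      c(r, 100 * r / denom)
    }
    full <- compute_rmse(ref, prd)
    sing <- sub_err(single)
    dbls <- sub_err(dbl)
    rows[[length(rows) + 1L]] <- tibble(
      cycle = cyc$cycle[i], start = cyc$start[i], end = cyc$end[i],
      rmse_full = full, rrmse_full = 100 * full / denom,
      rmse_single = sing[1], rrmse_single = sing[2],
      rmse_double = dbls[1], rrmse_double = dbls[2],
      vp1_ref = ref_cp$vp1_value, vp1_pred = vp1_p,
      tr_ref = ref_cp$tr_value, tr_pred = tr_p,
      vp2_ref = ref_cp$vp2_value, vp2_pred = vp2_p,
      rmse_vp1 = abs(ref_cp$vp1_value - vp1_p),
      rrmse_vp1 = 100 * abs(ref_cp$vp1_value - vp1_p) / denom,
      rmse_tr = abs(ref_cp$tr_value - tr_p),
      rrmse_tr = 100 * abs(ref_cp$tr_value - tr_p) / denom,
      rmse_vp2 = abs(ref_cp$vp2_value - vp2_p),
      rrmse_vp2 = 100 * abs(ref_cp$vp2_value - vp2_p) / denom)
  }
  if (length(rows) == 0) stop_data("no usable cycles in the supplied segment.")
  cycles <- dplyr::bind_rows(rows)

  phases <- c(full = "full", single = "single", double = "double",
              vp1 = "vp1", vp2 = "vp2", tr = "tr")
  summary <- dplyr::bind_rows(lapply(names(phases), function(ph) {
    r <- cycles[[paste0("rmse_", ph)]]
    rr <- cycles[[paste0("rrmse_", ph)]]
    tibble(phase = ph,
           rmse_mean = mean(r, na.rm = TRUE), rmse_sd = sd(r, na.rm = TRUE),
           rrmse_mean = mean(rr, na.rm = TRUE), rrmse_sd = sd(rr, na.rm = TRUE))
  }))
  structure(list(foot = foot, cycles = cycles, summary = summary,
                 rho = cor(reference[ok], predicted[ok]),
                 n_cycles = nrow(cycles), n_degenerate = n_degenerate,
                 rrmse_scope = rrmse_scope),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("# error report (%s foot): %d cycles (%d degenerate), rho = %.4f\n",
              x$foot, x$n_cycles, x$n_degenerate, x$rho))
  print(x$summary, ...)
  invisible(x)
}

#' Fit-and-evaluate convenience wrapper
#'
#' Predicts on a held-out recording and builds per-foot
#' [cycle_error_report()]s against its reference vGRF.
#'
#' @param fit a [fit_proxy()] result.
#' @param data held-out [grf_recording()] with reference vGRF.
#' @param events optional externally supplied events.
#' @return a `proxy_eval` list: `left`, `right` error reports and the
#'   `predictions` tibble.
#' @export
evaluate_proxy <- function(fit, data, events = NULL) {
  if (!has_reference(data)) {
    stop_structure("evaluation requires reference vGRF columns.")
  }
  events <- events %||% detect_gait_events(
    data, threshold = fit$config$event_threshold,
    min_phase = fit$config$min_phase)
  pred <- predict(fit, data, events = events)
  structure(list(
    left = cycle_error_report(data$grf_left, pred$grf_left, events, "left",
                              rrmse_scope = fit$config$rrmse_scope),
    right = cycle_error_report(data$grf_right, pred$grf_right, events, "right",
                               rrmse_scope = fit$config$rrmse_scope),
    predictions = pred, events = events, reference = data),
    class = "proxy_eval")
}

#' @export
print.proxy_eval <- function(x, ...) {
  cat(sprintf("# proxy evaluation: full-cycle rRMSE %.2f%% (left) / %.2f%% (right)\n",
              x$left$summary$rrmse_mean[x$left$summary$phase == "full"],
              x$right$summary$rrmse_mean[x$right$summary$phase == "full"]))
  invisible(x)
}

#' Compare two error samples with a pooled-variance t-test
#'
#' Two-sided two-sample Student's t-test (pooled variance) for comparing
#' prediction-error samples across walking tasks, sensor locations or
#' subjects; also reports group means and the variance between the group
#' means. Two zero-variance samples with equal means give `t = 0, p = 1` by
#' convention.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param labels two group labels.
#' @return one-row tibble: labels, group sizes and means, mean difference,
#'   between-group variance, `statistic`, `df`, `p_value`.
#' @export
compare_error_samples <- function(sample_a, sample_b, labels = c("A", "B")) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop_data("each sample needs at least two observations.")
  }
  ma <- mean(sample_a); mb <- mean(sample_b)
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    tt <- list(statistic = if (ma == mb) 0 else sign(ma - mb) * Inf,
               parameter = length(sample_a) + length(sample_b) - 2,
               p.value = if (ma == mb) 1 else 0)
  } else {
    tt <- t.test(sample_a, sample_b, var.equal = TRUE)
  }
  tibble(group_a = labels[1], group_b = labels[2],
         n_a = length(sample_a), n_b = length(sample_b),
         mean_a = ma, mean_b = mb, mean_diff = ma - mb,
         between_var = stats::var(c(ma, mb)),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}

terms_to_json_list <- function(terms) {
  lapply(seq_len(nrow(terms)), function(i) {
    factors <- list()
    if (!is.na(terms$chan1[i])) {
      factors[[1]] <- list(channel = terms$chan1[i],
                           lag = terms$lag1[i], power = terms$pow1[i])
    }
    if (!is.na(terms$chan2[i])) {
      factors[[length(factors) + 1]] <- list(channel = terms$chan2[i],
                                             lag = terms$lag2[i],
                                             power = terms$pow2[i])
    }
    list(factors = factors, coefficient = terms$coefficient[i])
  })
}

json_list_to_terms <- function(lst) {
  dplyr::bind_rows(lapply(lst, function(t) {
    f <- t$factors
    tibble(chan1 = if (length(f) >= 1) f[[1]]$channel else NA_character_,
           lag1 = if (length(f) >= 1) as.integer(f[[1]]$lag) else NA_integer_,
           pow1 = if (length(f) >= 1) as.integer(f[[1]]$power) else NA_integer_,
           chan2 = if (length(f) >= 2) f[[2]]$channel else NA_character_,
           lag2 = if (length(f) >= 2) as.integer(f[[2]]$lag) else NA_integer_,
           pow2 = if (length(f) >= 2) as.integer(f[[2]]$power) else NA_integer_,
           coefficient = t$coefficient)
  }))
}

#' Save / load fitted models as JSON
#'
#' Terms are serialized as factor lists `{channel, lag, power}` with their
#' coefficients at full double precision, so a save/load round trip yields
#' identical predictions. A `proxy_fit` stores both feet's models in one
#' file.
#'
#' @param model an `nma_model` or `proxy_fit`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "proxy_fit")) {
    list(type = "proxy_fit",
         left = model_to_list(model$left), right = model_to_list(model$right))
  } else if (inherits(model, "nma_model")) {
    c(list(type = "nma_model"), model_to_list(model))
  } else {
    stop_structure("`model` must be an nma_model or proxy_fit.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(model)
}

model_to_list <- function(m) {
  list(max_lag = m$max_lag, channels = as.list(m$channels),
       metadata = m$metadata, terms = terms_to_json_list(m$terms))
}

list_to_model <- function(lst) {
  nma_model(json_list_to_terms(lst$terms), max_lag = lst$max_lag,
            channels = unlist(lst$channels), metadata = lst$metadata)
}

#' @rdname save_model
#' @return `load_model()` returns the stored `nma_model`, or a named list
#'   `left`/`right` of models for a stored `proxy_fit`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (identical(obj$type, "proxy_fit")) {
    list(left = list_to_model(obj$left), right = list_to_model(obj$right))
  } else if (identical(obj$type, "nma_model")) {
    list_to_model(obj)
  } else {
    stop_structure(paste0("unrecognized model file: ", path))
  }
}
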