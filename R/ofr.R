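#' Stopping rule for forward term selection
#'
#' Exactly one mode is active: `fixed_terms` stops after `n_terms` terms
#' (the paper-scale default is a 64-term model); `err_threshold` stops once
#' the unexplained fraction of target energy `1 - sum(ERR)` falls to
#' `err_tolerance`; `information_criterion` stops when the penalized
#' criterion `n log(RSS/n) + penalty * n_terms` stops decreasing (default
#' penalty `log(n)`, BIC-like).
#'
#' @param mode one of `"fixed_terms"`, `"err_threshold"`,
#'   `"information_criterion"`.
#' @param n_terms model size for `fixed_terms`; also an upper cap for the
#'   other modes.
#' @param err_tolerance unexplained-energy tolerance for `err_threshold`.
#' @param penalty per-term penalty for `information_criterion`; `NULL` means
#'   `log(n)`.
#' @return a `stopping_rule` object.
#' @export
stopping_rule <- function(mode = c("fixed_terms", "err_threshold",
                                   "information_criterion"),
                          n_terms = 64, err_tolerance = 1e-10,
                          penalty = NULL) {
  mode <- match.arg(mode)
  if (n_terms < 1) stop_param("`n_terms` must be >= 1.")
  structure(list(mode = mode, n_terms = as.integer(n_terms),
                 err_tolerance = err_tolerance, penalty = penalty),
            class = "stopping_rule")
}

#' Orthogonal forward regression with error-reduction-ratio ranking
#'
#' Greedy structure selection over a candidate design matrix: at each step
#' every unselected candidate is orthogonalized against the already-selected
#' set (modified Gram--Schmidt, realized through its inner-product form with
#' an explicit re-orthogonalization pass on the admitted column), the error
#' reduction ratio
#' \eqn{ERR_i = g_i^2 \langle w_i, w_i\rangle / \langle y, y\rangle}
#' is computed from the orthogonalized candidate \eqn{w_i}, and the
#' candidate with maximal ERR is admitted (ties break toward the lowest
#' column index). Selection stops per the [stopping_rule()]. Final
#' coefficients in the original basis are recovered by back-substitution and
#' equal the least-squares solution on the selected support.
#'
#' @param design candidate matrix (rows = usable sample instants, columns =
#'   dictionary terms), e.g. from [evaluate_dictionary()].
#' @param target response vector (vGRF at the design's sample instants).
#' @param stop a [stopping_rule()].
#' @param forced_first optional column indices admitted, in order, before
#'   any free selection (used by [iofr_select()]).
#' @param degeneracy_tol candidates whose orthogonalized relative norm falls
#'   below this are skipped as degenerate.
#' @return an `ofr_result`: `terms` (selected column indices in order),
#'   `err`, `g` (orthogonal coefficients), `theta` (coefficients in the
#'   original basis), `rss`, `sum_err`, `ortho` (orthonormal basis of the
#'   selected columns), `truncated` flag.
#' @export
ofr_select <- function(design, target, stop = stopping_rule(),
                       forced_first = NULL, degeneracy_tol = 1e-10) {
  y <- as.numeric(target)
  n <- nrow(design)
  M <- ncol(design)
  if (length(y) != n) {
    stop_structure("`target` length must equal the number of design rows.")
  }
  yy <- sum(y^2)
  d_orig <- colSums(design^2)
  if (all(d_orig <= .Machine$double.eps * n)) {
    stop_data("no candidate column has positive norm.")
  }
  forced_first <- as.integer(forced_first %||% integer(0))
  if (any(forced_first < 1 | forced_first > M)) {
    stop_param("`forced_first` indices out of range.")
  }

  max_k <- min(stop$n_terms, M, n)
  d <- d_orig
  cy <- as.vector(crossprod(design, y))
  Q <- matrix(0, n, max_k)
  Cmat <- matrix(0, max_k, M)
  selected <- integer(0)
  g_norm <- numeric(0)
  err <- numeric(0)
  dead <- rep(FALSE, M)
  rss_run <- yy
  penalty <- stop$penalty %||% log(n)
  ic_prev <- Inf
  truncated <- FALSE
  drop_last <- FALSE

  while (yy > 0 && length(selected) < max_k) {
    k <- length(selected)
    forced <- k < length(forced_first)
    if (forced) {
      j <- forced_first[k + 1L]
    } else {
      score <- cy^2 / (d * yy)
      score[dead | d <= 0] <- -Inf
      if (length(selected) > 0) score[selected] <- -Inf
      j <- which.max(score)
      if (!is.finite(score[j])) { truncated <- TRUE; break }
    }
    # explicit orthogonalization of the admitted column (repeated once for
    # numerical orthogonality of the retained basis)
    pj <- design[, j]
    q <- pj
    if (k > 0) {
      Qk <- Q[, seq_len(k), drop = FALSE]
      q <- q - Qk %*% crossprod(Qk, q)
      q <- q - Qk %*% crossprod(Qk, q)
    }
    nq2 <- sum(q^2)
    if (nq2 < degeneracy_tol^2 * max(d_orig[j], .Machine$double.xmin)) {
      if (forced) stop_param("a forced-first term is degenerate on this design.")
      dead[j] <- TRUE
      d[j] <- 0
      next
    }
    q <- q / sqrt(nq2)
    gq <- sum(q * y)

    k <- k + 1L
    selected <- c(selected, j)
    Q[, k] <- q
    cj <- as.vector(crossprod(design, q))
    Cmat[k, ] <- cj
    d <- pmax(d - cj^2, 0)
    cy <- cy - gq * cj
    g_norm <- c(g_norm, gq)
    err <- c(err, if (yy > 0) gq^2 / yy else 0)
    rss_run <- max(rss_run - gq^2, 0)

    if (k >= length(forced_first)) {
      if (stop$mode == "fixed_terms" && k >= stop$n_terms) break
      if (stop$mode == "err_threshold" &&
          (yy == 0 || 1 - sum(err) <= stop$err_tolerance)) break
      if (stop$mode == "information_criterion") {
        ic <- n * log(max(rss_run, .Machine$double.xmin) / n) + penalty * k
        if (ic >= ic_prev) { drop_last <- TRUE; break }
        ic_prev <- ic
      }
    }
  }
  if (drop_last && length(selected) > length(forced_first)) {
    k <- length(selected) - 1L
    selected <- selected[seq_len(k)]
    g_norm <- g_norm[seq_len(k)]
    err <- err[seq_len(k)]
  }
  k <- length(selected)
  if (k == 0) {
    theta <- numeric(0)
    rss <- yy
    Qk <- matrix(0, n, 0)
    Rk <- matrix(0, 0, 0)
  } else {
    Qk <- Q[, seq_len(k), drop = FALSE]
    Rk <- matrix(0, k, k)
    for (t in seq_len(k)) Rk[seq_len(t), t] <- Cmat[seq_len(t), selected[t]]
    theta <- backsolve(Rk, g_norm)
    rss <- sum((y - design[, selected, drop = FALSE] %*% theta)^2)
  }
  structure(list(terms = selected,
                 err = err,
                 g = if (k > 0) g_norm / diag(Rk) else numeric(0),
                 theta = as.vector(theta),
                 rss = rss, sum_err = sum(err), yy = yy, n = n,
                 ortho = Qk, r_mat = Rk,
                 forced = forced_first, stop = stop,
                 truncated = truncated,
                 dictionary = attr(design, "dictionary")),
            class = "ofr_result")
}

#' Iterative orthogonal forward regression
#'
#' Escapes greedy suboptima by restarting: iteration 0 is plain
#' [ofr_select()]; each subsequent iteration re-runs the selection once per
#' term of the current model with that term forced first, and the
#' minimal-RSS candidate of equal model size replaces the current model when
#' strictly better. Terminates at a fixed point or after `max_iterations`.
#' The result's RSS never exceeds plain OFR's.
#'
#' @inheritParams ofr_select
#' @param max_iterations maximum number of restart sweeps.
#' @return an `ofr_result` with extra fields `iterations` and `base_rss`
#'   (plain OFR's RSS).
#' @export
iofr_select <- function(design, target, stop = stopping_rule(),
                        max_iterations = 10, degeneracy_tol = 1e-10) {
  best <- ofr_select(design, target, stop, degeneracy_tol = degeneracy_tol)
  base_rss <- best$rss
  iterations <- 0L
  repeat {
    if (iterations >= max_iterations || length(best$terms) == 0) break
    cands <- lapply(best$terms, function(t) {
      ofr_select(design, target, stop, forced_first = t,
                 degeneracy_tol = degeneracy_tol)
    })
    cands <- Filter(function(cand) length(cand$terms) == length(best$terms), cands)
    iterations <- iterations + 1L
    if (length(cands) == 0) break
    rss <- vapply(cands, `[[`, numeric(1), "rss")
    champ <- cands[[which.min(rss)]]
    # strict improvement, judged relative to the target energy so that
    # machine-noise differences between already-perfect fits do not cycle
    if (champ$rss < best$rss - 1e-12 * max(best$yy, .Machine$double.xmin)) {
      best <- champ
    } else {
      break
    }
  }
  best$iterations <- iterations
  best$base_rss <- base_rss
  best
}

#' @export
print.ofr_result <- function(x, ...) {
  cat(sprintf("# OFR model: %d terms, sum ERR = %.6f, RSS = %.6g%s\n",
              length(x$terms), x$sum_err, x$rss,
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  invisible(x)
}

#' Construct a nonlinear moving-average (Volterra) model
#'
#' A fitted proxy model: a sparse set of degree-at-most-2 monomials in
#' lagged input channels, each with a real coefficient. Prediction uses
#' inputs only — no output feedback — so errors never accumulate.
#'
#' @param terms tibble of monomials (`chan1`, `lag1`, `pow1`, `chan2`,
#'   `lag2`, `pow2`) with a `coefficient` column.
#' @param max_lag maximum lag; default the largest lag referenced.
#' @param channels channel names the model may reference.
#' @param metadata free-form list (training configuration, seed, ...).
#' @return an `nma_model`.
#' @export
nma_model <- function(terms, max_lag = NULL, channels = NULL,
                      metadata = list()) {
  terms <- as_tibble(terms)
  if (!"coefficient" %in% names(terms)) {
    stop_structure("`terms` must carry a coefficient column.")
  }
  deg <- ifelse(is.na(terms$chan1), 0L,
                terms$pow1 + dplyr::coalesce(terms$pow2, 0L))
  if (any(deg > 2)) stop_param("model terms must have total degree <= 2.")
  lags_used <- c(terms$lag1, terms$lag2)
  max_lag <- as.integer(max_lag %||% max(c(lags_used, 0L), na.rm = TRUE))
  channels <- channels %||%
    sort(unique(stats::na.omit(c(terms$chan1, terms$chan2))))
  if (!"label" %in% names(terms)) terms$label <- term_labels(terms)
  structure(list(terms = terms, max_lag = max_lag, channels = channels,
                 metadata = metadata),
            class = "nma_model")
}

ofr_to_nma <- function(ofr, dictionary, metadata = list()) {
  tbl <- dictionary$terms[ofr$terms, , drop = FALSE]
  tbl$coefficient <- ofr$theta
  tbl$err <- ofr$err
  nma_model(tbl, max_lag = dictionary$max_lag,
            channels = dictionary$channels, metadata = metadata)
}

#' Predict vGRF from an NMA model
#'
#' Deterministic evaluation of the model polynomial at each sample instant
#' `k >= max_lag`, using only current and lagged inputs; the first `max_lag`
#' entries of the result are `NA` (their lags precede the recording).
#'
#' @param model an [nma_model()].
#' @param signals data frame holding every channel the model references
#'   (e.g. from [decompose_acceleration()]).
#' @return numeric vector as long as `signals`.
#' @export
predict_nma <- function(model, signals) {
  stopifnot(inherits(model, "nma_model"))
  n <- nrow(signals)
  L <- model$max_lag
  if (n <= L) stop_data("signals shorter than the model's max lag.")
  missing_ch <- setdiff(model$channels, names(signals))
  if (length(missing_ch) > 0) {
    stop_structure(paste0("signals are missing channel(s): ",
                          paste(missing_ch, collapse = ", ")))
  }
  out <- rep(NA_real_, n)
  if (nrow(model$terms) > 0) {
    tv <- eval_term_matrix(model$terms, signals, L)
    out[(L + 1L):n] <- as.vector(tv %*% model$terms$coefficient)
  } else {
    out[(L + 1L):n] <- 0
  }
  out
}

#' @export
print.nma_model <- function(x, ...) {
  cat(sprintf("# NMA model: %d terms, max lag %d, channels: %s\n",
              nrow(x$terms), x$max_lag, paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Choose a maximum lag by input-output cross-correlation
#'
#' Computes the normalized cross-correlation between an acceleration channel
#' and the total vGRF over lags `0..max_lag`, keeps the lags whose
#' correlation exceeds the 95% white-noise band `1.96/sqrt(N)`, and returns
#' the smallest lag window containing `energy_fraction` of the significant
#' squared-correlation mass.
#'
#' @param x input (acceleration) series.
#' @param y output (total vGRF) series, same length.
#' @param max_lag largest lag scanned.
#' @param energy_fraction fraction of significant correlation mass the
#'   returned window must contain (default 0.95).
#' @return a `lag_analysis` list: `max_lag` (the estimate), `dominant_lag`,
#'   and a `trace` tibble (`lag`, `correlation`, `band`, `significant`).
#' @export
max_lag_by_crosscorrelation <- function(x, y, max_lag = 40,
                                        energy_fraction = 0.95) {
  if (length(x) != length(y)) stop_structure("`x` and `y` must have equal length.")
  if (length(x) <= max_lag + 2) stop_data("series too short for the lag range.")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_domain("constant input: cross-correlation undefined.")
  }
  N <- length(x)
  lags <- 0:max_lag
  r <- vapply(lags, function(l) {
    cor(x[seq_len(N - l)], y[seq_len(N - l) + l])
  }, numeric(1))
  band <- 1.96 / sqrt(N)
  sig <- abs(r) > band
  mass <- r^2 * as.numeric(sig)
  if (sum(mass) == 0) mass <- r^2  # nothing significant: fall back to raw mass
  cum <- cumsum(mass) / sum(mass)
  est <- lags[match(TRUE, cum >= energy_fraction)]
  structure(list(max_lag = est,
                 dominant_lag = lags[which.max(abs(r))],
                 energy_fraction = energy_fraction,
                 trace = tibble(lag = lags, correlation = r, band = band,
                                significant = sig)),
            class = "lag_analysis")
}

#' @export
print.lag_analysis <- function(x, ...) {
  cat(sprintf("# lag analysis: dominant lag %d, %g%% correlation mass within lag %d\n",
              x$dominant_lag, 100 * x$energy_fraction, x$max_lag))
  invisible(x)
}

#' Higher-order cross-correlation nonlinearity diagnostic
#'
#' Fits the best linear-in-lags model of the target on the input (lags
#' `0..max_lag` plus intercept), then cross-correlates the squared centred
#' input with the residuals over the same lags. Any excursion beyond the
#' `±1.96/sqrt(N)` band indicates structure a linear model cannot capture,
#' and the verdict is `"nonlinear"`.
#'
#' @param u input series.
#' @param y target series, same length.
#' @param max_lag largest lag used for both the linear fit and the
#'   diagnostic trace.
#' @return a `nonlinearity_test` list: `verdict`, `band`, and `trace`
#'   (`lag`, `statistic`).
#' @export
nonlinearity_test <- function(u, y, max_lag = 18) {
  if (length(u) != length(y)) stop_structure("`u` and `y` must have equal length.")
  N <- length(u)
  L <- as.integer(max_lag)
  if (N <= 3L * (L + 2L)) stop_data("series too short for a stable linear fit.")
  rows <- (L + 1L):N
  U <- vapply(0:L, function(l) u[rows - l], numeric(length(rows)))
  fit <- lm.fit(cbind(1, U), y[rows])
  e <- fit$residuals
  s <- (u - mean(u))^2
  s <- s - mean(s)
  r <- vapply(0:L, function(l) {
    sl <- s[rows - l]
    if (sd(sl) == 0 || sd(e) == 0) return(0)
    cor(sl, e)
  }, numeric(1))
  band <- 1.96 / sqrt(length(e))
  structure(list(verdict = if (any(abs(r) > band)) "nonlinear" else "linear",
                 band = band,
                 trace = tibble(lag = 0:L, statistic = r)),
            class = "nonlinearity_test")
}

#' @export
print.nonlinearity_test <- function(x, ...) {
  cat(sprintf("# nonlinearity diagnostic: verdict %s (band ±%.4f, max |stat| %.4f)\n",
              x$verdict, x$band, max(abs(x$trace$statistic))))
  invisible(x)
}
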