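# Monomial terms are rows with at most two factors (degree <= 2):
# (chan1, lag1, pow1) and optionally (chan2, lag2, pow2). The constant term
# has chan1 = NA. Canonical form sorts the two factors by (channel, lag) and
# merges equal factors into a squared single factor, so u(k)*u(k-1) and
# u(k-1)*u(k) land on one column.
canonicalize_terms <- function(terms) {
  if (nrow(terms) == 0) return(terms)
  for (i in seq_len(nrow(terms))) {
    if (is.na(terms$chan2[i])) next
    f1 <- c(terms$chan1[i], terms$lag1[i])
    f2 <- c(terms$chan2[i], terms$lag2[i])
    if (identical(f1, f2) ||
        (terms$chan1[i] == terms$chan2[i] && terms$lag1[i] == terms$lag2[i])) {
      terms$pow1[i] <- terms$pow1[i] + terms$pow2[i]
      terms$chan2[i] <- NA_character_
      terms$lag2[i] <- NA_integer_
      terms$pow2[i] <- NA_integer_
    } else if (terms$chan2[i] < terms$chan1[i] ||
               (terms$chan2[i] == terms$chan1[i] && terms$lag2[i] < terms$lag1[i])) {
      terms[i, c("chan1", "lag1", "pow1", "chan2", "lag2", "pow2")] <-
        terms[i, c("chan2", "lag2", "pow2", "chan1", "lag1", "pow1")]
    }
  }
  terms
}

term_labels <- function(terms) {
  fac <- function(ch, lag, pow) {
    base <- ifelse(lag == 0, paste0(ch, "(k)"), paste0(ch, "(k-", lag, ")"))
    ifelse(pow > 1, paste0(base, "^", pow), base)
  }
  out <- character(nrow(terms))
  for (i in seq_len(nrow(terms))) {
    if (is.na(terms$chan1[i])) {
      out[i] <- "1"
    } else if (is.na(terms$chan2[i])) {
      out[i] <- fac(terms$chan1[i], terms$lag1[i], terms$pow1[i])
    } else {
      out[i] <- paste0(fac(terms$chan1[i], terms$lag1[i], terms$pow1[i]), "*",
                       fac(terms$chan2[i], terms$lag2[i], terms$pow2[i]))
    }
  }
  out
}

#' Build the candidate monomial dictionary
#'
#' Enumerates every distinct monomial of total degree at most `max_degree`
#' in the lagged channels `channel(k - lag)`, `lag = 0..max_lag`: with
#' `m = length(channels) * (max_lag + 1)` lagged variables the dictionary
#' holds the constant (optional), the `m` linear terms, and — at degree 2 —
#' all `m (m + 1) / 2` unordered quadratic products, for
#' `1 + m + m (m + 1) / 2` terms in total.
#'
#' @param channels character vector of input channel names (typically the
#'   six decomposed acceleration channels).
#' @param max_lag maximum lag in samples (paper-scale default elsewhere: 18).
#' @param max_degree 1 or 2.
#' @param include_constant include the constant term?
#' @return a `term_dictionary` object.
#' @export
build_dictionary <- function(channels = decomposed_channels(), max_lag = 18,
                             max_degree = 2, include_constant = TRUE) {
  if (!max_degree %in% c(1, 2)) {
    stop_param("`max_degree` must be 1 or 2; the model class is quadratic at most.")
  }
  if (max_lag < 0) stop_param("`max_lag` must be >= 0.")
  vars <- tidyr::expand_grid(chan = channels, lag = 0:max_lag)
  # channel-major, lag-increasing variable order fixes term indices
  vars <- dplyr::arrange(vars, match(.data$chan, channels), .data$lag)
  m <- nrow(vars)

  terms <- list()
  if (include_constant) {
    terms$const <- tibble(chan1 = NA_character_, lag1 = NA_integer_,
                          pow1 = NA_integer_, chan2 = NA_character_,
                          lag2 = NA_integer_, pow2 = NA_integer_)
  }
  terms$linear <- tibble(chan1 = vars$chan, lag1 = as.integer(vars$lag),
                         pow1 = 1L, chan2 = NA_character_,
                         lag2 = NA_integer_, pow2 = NA_integer_)
  if (max_degree == 2) {
    idx <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
    i <- idx[, "row"]; j <- idx[, "col"]
    ord <- order(i, j)
    i <- i[ord]; j <- j[ord]
    quad <- tibble(chan1 = vars$chan[i], lag1 = as.integer(vars$lag[i]),
                   pow1 = 1L,
                   chan2 = vars$chan[j], lag2 = as.integer(vars$lag[j]),
                   pow2 = 1L)
    same <- i == j
    quad$pow1[same] <- 2L
    quad$chan2[same] <- NA_character_
    quad$lag2[same] <- NA_integer_
    quad$pow2[same] <- NA_integer_
    terms$quad <- quad
  }
  tbl <- dplyr::bind_rows(terms)
  tbl <- dplyr::mutate(tbl, term = dplyr::row_number(),
                       label = term_labels(tbl), .before = 1)
  structure(list(terms = tbl, channels = channels,
                 max_lag = as.integer(max_lag),
                 max_degree = as.integer(max_degree),
                 include_constant = include_constant),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("# term dictionary: %d terms (%d channels, lags 0..%d, degree <= %d%s)\n",
              nrow(x$terms), length(x$channels), x$max_lag, x$max_degree,
              if (x$include_constant) ", constant" else ""))
  print(x$terms, ...)
  invisible(x)
}

# Evaluate monomial rows on decomposed signals at k = L..N-1 (0-based).
# Returns an (N - L) x n_terms matrix of term values, coefficients excluded.
eval_term_matrix <- function(terms, signals, max_lag) {
  n <- nrow(signals)
  L <- as.integer(max_lag)
  if (n <= L) stop_data("signal length must exceed max_lag.")
  rows <- (L + 1L):n
  out <- matrix(1, nrow = length(rows), ncol = nrow(terms))
  for (t in seq_len(nrow(terms))) {
    if (!is.na(terms$chan1[t])) {
      ch <- signals[[terms$chan1[t]]]
      if (is.null(ch)) {
        stop_structure(paste0("channel `", terms$chan1[t], "` missing from signals."))
      }
      v <- ch[rows - terms$lag1[t]]
      out[, t] <- if (terms$pow1[t] == 1) v else v^terms$pow1[t]
    }
    if (!is.na(terms$chan2[t])) {
      ch <- signals[[terms$chan2[t]]]
      if (is.null(ch)) {
        stop_structure(paste0("channel `", terms$chan2[t], "` missing from signals."))
      }
      v <- ch[rows - terms$lag2[t]]
      out[, t] <- out[, t] * (if (terms$pow2[t] == 1) v else v^terms$pow2[t])
    }
  }
  out
}

#' Evaluate a dictionary into a design matrix
#'
#' One row per usable sample instant `k = max_lag .. N-1`, one column per
#' dictionary term; entries are the monomial values at `k`. No entry
#' references a sample before `k - max_lag` or after `k` (input terms only,
#' strictly causal).
#'
#' @param dictionary a [build_dictionary()] object.
#' @param signals data frame holding every channel the dictionary names
#'   (e.g. from [decompose_acceleration()]).
#' @return numeric matrix with attributes `k` (the 0-based sample instants)
#'   and `dictionary`.
#' @export
evaluate_dictionary <- function(dictionary, signals) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  missing_ch <- setdiff(dictionary$channels, names(signals))
  if (length(missing_ch) > 0) {
    stop_structure(paste0("signals are missing channel(s): ",
                          paste(missing_ch, collapse = ", ")))
  }
  n <- nrow(signals)
  L <- dictionary$max_lag
  if (n <= L) stop_data("signal length must exceed the dictionary max_lag.")
  # build the m lagged-variable columns once, then form products
  rows <- (L + 1L):n
  vars <- tidyr::expand_grid(chan = dictionary$channels, lag = 0:L)
  vars <- dplyr::arrange(vars, match(.data$chan, dictionary$channels), .data$lag)
  V <- matrix(0, nrow = length(rows), ncol = nrow(vars))
  for (v in seq_len(nrow(vars))) {
    V[, v] <- signals[[vars$chan[v]]][rows - vars$lag[v]]
  }
  key <- paste(vars$chan, vars$lag)
  vindex <- function(ch, lag) match(paste(ch, lag), key)

  tbl <- dictionary$terms
  X <- matrix(1, nrow = length(rows), ncol = nrow(tbl))
  for (t in seq_len(nrow(tbl))) {
    if (is.na(tbl$chan1[t])) next
    v1 <- V[, vindex(tbl$chan1[t], tbl$lag1[t])]
    X[, t] <- if (tbl$pow1[t] == 1) v1 else v1^tbl$pow1[t]
    if (!is.na(tbl$chan2[t])) {
      X[, t] <- X[, t] * V[, vindex(tbl$chan2[t], tbl$lag2[t])]
    }
  }
  colnames(X) <- tbl$label
  attr(X, "k") <- (rows - 1L)
  attr(X, "dictionary") <- dictionary
  X
}
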