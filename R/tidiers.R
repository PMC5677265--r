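#' Tidy a fitted NMA model
#'
#' @param x an `nma_model`.
#' @param ... unused.
#' @return tibble with one row per model term: `term` (label), the monomial
#'   factors, `estimate`, and `err` when the selection trace is attached.
#' @export
tidy.nma_model <- function(x, ...) {
  out <- dplyr::rename(x$terms, estimate = "coefficient")
  dplyr::relocate(out, dplyr::any_of(c("term", "label", "estimate", "err")))
}

#' @rdname tidy.nma_model
#' @export
glance.nma_model <- function(x, ...) {
  tibble(n_terms = nrow(x$terms), max_lag = x$max_lag,
         n_channels = length(x$channels),
         sum_err = if ("err" %in% names(x$terms)) sum(x$terms$err) else NA_real_)
}

#' Tidy an OFR selection trace
#'
#' @param x an `ofr_result`.
#' @param ... unused.
#' @return tibble with one row per selection step: `step`, the selected
#'   column index `term`, `label` when a dictionary is attached, `err`,
#'   orthogonal coefficient `g`, and final coefficient `estimate`.
#' @export
tidy.ofr_result <- function(x, ...) {
  out <- tibble(step = seq_along(x$terms), term = x$terms,
                err = x$err, g = x$g, estimate = x$theta)
  if (!is.null(x$dictionary)) {
    out$label <- x$dictionary$terms$label[x$terms]
    out <- dplyr::relocate(out, "step", "term", "label")
  }
  out
}

#' @rdname tidy.ofr_result
#' @export
glance.ofr_result <- function(x, ...) {
  tibble(n_terms = length(x$terms), rss = x$rss, sum_err = x$sum_err,
         r_squared = if (x$yy > 0) 1 - x$rss / x$yy else NA_real_,
         truncated = x$truncated,
         iterations = x$iterations %||% NA_integer_,
         base_rss = x$base_rss %||% NA_real_)
}

#' Tidy a bilateral proxy fit
#'
#' @param x a `proxy_fit`.
#' @param ... unused.
#' @return tibble of both feet's model terms with a `foot` column.
#' @export
tidy.proxy_fit <- function(x, ...) {
  dplyr::bind_rows(left = tidy(x$left), right = tidy(x$right), .id = "foot")
}

#' @rdname tidy.proxy_fit
#' @export
glance.proxy_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(c("left", "right"), function(f) {
    g <- glance(x[[paste0("ofr_", f)]])
    dplyr::mutate(g, foot = f, .before = 1)
  }))
}

#' Tidy an error report
#'
#' @param x an `error_report` (or `proxy_eval`).
#' @param ... unused.
#' @return the aggregate mean ± SD table (one row per phase / critical
#'   point); for a `proxy_eval`, both feet stacked with a `foot` column.
#' @export
tidy.error_report <- function(x, ...) x$summary

#' @rdname tidy.error_report
#' @export
glance.error_report <- function(x, ...) {
  tibble(foot = x$foot, rho = x$rho, n_cycles = x$n_cycles,
         n_degenerate = x$n_degenerate,
         rrmse_full_mean = x$summary$rrmse_mean[x$summary$phase == "full"])
}

#' @rdname tidy.error_report
#' @export
tidy.proxy_eval <- function(x, ...) {
  dplyr::bind_rows(left = tidy(x$left), right = tidy(x$right), .id = "foot")
}

#' @rdname tidy.error_report
#' @export
glance.proxy_eval <- function(x, ...) {
  dplyr::bind_rows(glance(x$left), glance(x$right))
}
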