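# Shared fixtures, all generated in code.

# Events describing left stance [0, 10) and right stance [5, 15): a 5-sample
# double support from the right IC at k = 5.
two_stance_events <- function() {
  tibble::tibble(foot = c("left", "right", "left", "right"),
                 event = c("IC", "IC", "FC", "FC"),
                 k = c(0L, 5L, 10L, 15L))
}

# Alternating walking events over n_steps stances per foot with configurable
# stance length and double-support overlap (in samples).
walking_events <- function(n_steps = 3, stance = 40L, overlap = 8L) {
  period <- 2L * (stance - overlap)
  left_ic <- (seq_len(n_steps) - 1L) * period
  right_ic <- left_ic + stance - overlap
  tibble::tibble(
    foot = rep(c("left", "right"), each = 2L * n_steps),
    event = rep(rep(c("IC", "FC"), each = n_steps), 2L),
    k = c(left_ic, left_ic + stance, right_ic, right_ic + stance)
  ) |> dplyr::arrange(k)
}

# Exhaustive best-subset least squares: minimal RSS over all k-subsets.
best_subset_rss <- function(X, y, k) {
  combos <- utils::combn(ncol(X), k)
  min(apply(combos, 2, function(j) {
    fit <- stats::lm.fit(X[, j, drop = FALSE], y)
    sum(fit$residuals^2)
  }))
}

# A selection problem constructed to defeat greedy forward selection: the
# response lies exactly in the span of two orthonormal columns, while a decoy
# column aligned with their sum (plus a small orthogonal component) attracts
# the first greedy pick. The exhaustive best 2-subset has RSS 0.
greedy_trap <- function(seed, n = 60, p = 10, tilt = 0.15) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  x1 <- Q[, 1]; x2 <- Q[, 2]; xp <- Q[, 3]
  decoy <- cos(tilt) * (x1 + x2) / sqrt(2) + sin(tilt) * xp
  y <- x1 + 0.9 * x2
  X <- cbind(decoy, x1, x2, Q[, 4:p])
  colnames(X) <- paste0("c", seq_len(ncol(X)))
  list(X = X, y = y)
}

# Random oracle-model specification over the six decomposed channels.
random_oracle_spec <- function(seed, n_terms = 2, max_lag = 5) {
  set.seed(seed)
  ch <- grfproxy:::decomposed_channels()
  terms <- lapply(seq_len(n_terms), function(i) {
    if (runif(1) < 0.5) {
      oracle_term(runif(1, 0.5, 2) * sample(c(-1, 1), 1),
                  sample(ch, 1), sample(0:max_lag, 1))
    } else {
      oracle_term(runif(1, 0.2, 1) * sample(c(-1, 1), 1),
                  sample(ch, 1), sample(0:max_lag, 1), 1,
                  sample(ch, 1), sample(0:max_lag, 1), 1)
    }
  })
  do.call(oracle_spec, c(terms, list(max_lag = max_lag)))
}

# Term-set signature for support-recovery comparisons.
term_signature <- function(terms) {
  sort(paste(terms$chan1, terms$lag1, terms$pow1,
             terms$chan2, terms$lag2, terms$pow2))
}
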