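test_that("a perfect single-term fit is selected first with ERR = 1", {
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  y <- X[, 3]
  res <- ofr_select(X, y, stopping_rule("err_threshold", n_terms = 4))
  expect_equal(res$terms[1], 3L)
  expect_equal(res$err[1], 1, tolerance = 1e-12)
  expect_equal(res$sum_err, 1, tolerance = 1e-12)
  expect_equal(res$rss, 0, tolerance = 1e-20)
})

test_that("noiseless quadratic oracle structure and parameters are recovered exactly", {
  set.seed(7)
  n <- 500
  u <- rnorm(n)
  y <- c(0, 2 * u[-n]) - 0.5 * c(0, 0, u[-c(n - 1, n)])
  d <- build_dictionary("u", max_lag = 4, max_degree = 2)
  X <- evaluate_dictionary(d, tibble::tibble(u = u))
  res <- ofr_select(X, y[5:n], stopping_rule("err_threshold", n_terms = 10,
                                             err_tolerance = 1e-12))
  labels <- d$terms$label[res$terms]
  expect_setequal(labels, c("u(k-1)", "u(k-2)"))
  theta <- res$theta[order(match(labels, c("u(k-1)", "u(k-2)")))]
  expect_equal(theta, c(2, -0.5), tolerance = 1e-8)

  # back-substituted coefficients equal direct least squares on the support
  ls <- stats::lm.fit(X[, res$terms, drop = FALSE], y[5:n])
  expect_equal(res$theta, unname(ls$coefficients), tolerance = 1e-8)
})

test_that("ERR, orthogonality and least-squares consistency hold on random problems", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 80; p <- 20
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(5)
    y <- X[, 1:5] %*% beta + rnorm(n, 0, 0.5)
    res <- ofr_select(X, y, stopping_rule("fixed_terms", 10))
    expect_true(all(res$err >= 0 & res$err <= 1))
    expect_lte(res$sum_err, 1 + 1e-9)
    # monotone residual: cumulative ERR is non-decreasing
    expect_true(all(diff(cumsum(res$err)) >= -1e-12))

    G <- crossprod(res$ortho)
    offdiag <- G - diag(diag(G))
    expect_lt(max(abs(offdiag)), 1e-8)

    ls <- stats::lm.fit(X[, res$terms, drop = FALSE], y)
    expect_equal(res$theta, unname(ls$coefficients),
                 tolerance = 1e-8)
    expect_equal(res$rss, sum(ls$residuals^2), tolerance = 1e-8)
  }
})

test_that("degenerate (collinear) candidates are skipped", {
  set.seed(3)
  x <- rnorm(40)
  X <- cbind(x, x, rnorm(40))  # exact duplicate column
  y <- x + 0.1 * rnorm(40)
  res <- ofr_select(X, y, stopping_rule("fixed_terms", 3))
  expect_false(all(c(1, 2) %in% res$terms))
  expect_true(res$truncated)
})

test_that("greedy selection matches the exhaustive best subset when unambiguous", {
  set.seed(11)
  n <- 60
  Q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))  # orthogonal: greedy is optimal
  y <- 3 * Q[, 2] - 2 * Q[, 5] + Q[, 7]
  res <- ofr_select(Q, y, stopping_rule("fixed_terms", 3))
  expect_equal(res$rss, best_subset_rss(Q, y, 3), tolerance = 1e-10)
  expect_setequal(res$terms, c(2L, 5L, 7L))
})

test_that("iterative OFR is a fixed point on greedy-optimal data", {
  set.seed(12)
  n <- 60
  Q <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))
  y <- 3 * Q[, 2] - 2 * Q[, 5]
  plain <- ofr_select(Q, y, stopping_rule("fixed_terms", 2))
  it <- iofr_select(Q, y, stopping_rule("fixed_terms", 2))
  expect_equal(sort(it$terms), sort(plain$terms))
  expect_equal(it$rss, plain$rss)
  expect_equal(it$iterations, 1L)
})

test_that("iterative OFR escapes the greedy trap to the exhaustive optimum", {
  trap <- greedy_trap(seed = 101)
  stop2 <- stopping_rule("fixed_terms", 2)
  plain <- ofr_select(trap$X, trap$y, stop2)
  it <- iofr_select(trap$X, trap$y, stop2)
  best <- best_subset_rss(trap$X, trap$y, 2)
  expect_gt(plain$rss, best + 1e-6)          # greedy is fooled
  expect_equal(it$rss, best, tolerance = 1e-10)  # restarts recover the optimum
  expect_setequal(it$terms, c(2L, 3L))
})

test_that("iterative OFR never does worse than plain OFR", {
  for (seed in 1:25) {
    set.seed(seed + 500)
    n <- 50; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 2] + X[, 3] + 0.2 * rnorm(n)  # induce correlated candidates
    y <- X[, 2] - X[, 4] + 0.3 * rnorm(n)
    plain <- ofr_select(X, y, stopping_rule("fixed_terms", 3))
    it <- iofr_select(X, y, stopping_rule("fixed_terms", 3))
    expect_lte(it$rss, plain$rss + 1e-12)
  }
})

test_that("coefficients are recovered at the true support under 5% noise", {
  rel_err <- vapply(1:50, function(seed) {
    spec <- random_oracle_spec(seed, n_terms = 2, max_lag = 5)
    orc <- generate_oracle_recording(spec, 600, seed = seed + 1000)
    d <- build_dictionary(max_lag = 5)
    X <- evaluate_dictionary(d, orc$signals)
    y <- orc$grf_left[6:600]
    set.seed(seed + 2000)
    y <- y + rnorm(length(y), 0, 0.05 * stats::sd(y))
    res <- ofr_select(X, y, stopping_rule("fixed_terms", nrow(spec$terms)))
    sel <- d$terms[res$terms, ]
    sel$coefficient <- res$theta
    if (!identical(term_signature(sel), term_signature(spec$terms))) {
      return(NA_real_)
    }
    ord <- match(paste(sel$chan1, sel$lag1, sel$pow1, sel$chan2, sel$lag2, sel$pow2),
                 paste(spec$terms$chan1, spec$terms$lag1, spec$terms$pow1,
                       spec$terms$chan2, spec$terms$lag2, spec$terms$pow2))
    max(abs(sel$coefficient - spec$terms$coefficient[ord]) /
          abs(spec$terms$coefficient[ord]))
  }, numeric(1))
  expect_lt(stats::median(rel_err, na.rm = TRUE), 0.05)
  expect_gt(mean(!is.na(rel_err)), 0.8)  # support recovered in most instances
})

test_that("NMA prediction uses inputs only and closes on oracle data", {
  spec <- oracle_spec(oracle_term(1.2, "ay_right", 3),
                      oracle_term(0.4, "az_left", 0, 2))
  orc <- generate_oracle_recording(spec, 300, seed = 5)
  model <- nma_model(spec$terms, max_lag = spec$max_lag)
  pred <- predict_nma(model, orc$signals)
  k <- (spec$max_lag + 1):300
  expect_equal(pred[k], orc$grf_left[k], tolerance = 1e-14)
  expect_true(all(is.na(pred[seq_len(spec$max_lag)])))
  expect_error(predict_nma(model, orc$signals["ax_left"]),
               class = "grfproxy_error_structure")
})

test_that("cross-correlation lag analysis finds constructed delays", {
  set.seed(9)
  u <- rnorm(1000)
  y7 <- c(rep(0, 7), u[1:993]) + rnorm(1000, 0, 0.05)
  la <- max_lag_by_crosscorrelation(u, y7, max_lag = 20)
  expect_equal(la$dominant_lag, 7L)
  expect_gte(la$max_lag, 7L)

  y0 <- u + rnorm(1000, 0, 0.05)
  expect_equal(max_lag_by_crosscorrelation(u, y0, max_lag = 20)$dominant_lag, 0L)

  expect_error(max_lag_by_crosscorrelation(rep(1, 100), rnorm(100)),
               class = "grfproxy_error_domain")

  # independent white noise: significant excursions at chance level
  hits <- vapply(1:40, function(s) {
    set.seed(s + 300)
    a <- rnorm(400); b <- rnorm(400)
    sum(max_lag_by_crosscorrelation(a, b, max_lag = 10)$trace$significant)
  }, numeric(1))
  expect_lt(mean(hits > 2), 0.2)
})

test_that("the higher-order correlation diagnostic separates linear from quadratic maps", {
  set.seed(5)
  u <- rnorm(1500)
  y_lin <- 1.5 * c(0, u[-1500]) + 0.7 * u + rnorm(1500, 0, 0.3)
  lin <- nonlinearity_test(u, y_lin, max_lag = 10)
  expect_equal(lin$verdict, "linear")
  expect_lt(max(abs(lin$trace$statistic)), 2 * lin$band)

  y_sq <- c(0, u[-1500])^2 + rnorm(1500, 0, 0.1)
  nl <- nonlinearity_test(u, y_sq, max_lag = 10)
  expect_equal(nl$verdict, "nonlinear")
  expect_true(all(abs(nl$trace$statistic) <= 1))
})
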