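fit_small <- function(seed, n = 40, target_fun = NULL, epochs = 400) {
  set.seed(seed)
  x <- matrix(runif(n * 5, 1, 5), n, 5)
  colnames(x) <- trait_names_for_test()
  y <- if (is.null(target_fun)) sample(1:4, n, TRUE) else target_fun(x)
  spec <- model_spec(1)
  spec$n_classes <- length(unique(c(y, 1:4)))
  fit <- train_network(spec, x, y, train_config(max_epochs = epochs, seed = seed))
  list(fit = fit, x = x, y = y)
}

test_that("a dead input (zero outgoing weights) has sensitivity ratio 1", {
  f <- fit_small(1)
  fit <- f$fit
  fit$w_ih[2, ] <- 0  # sever input 2 from the hidden layer
  sr <- sensitivity_ratios(fit, f$x, f$y)
  expect_equal(sr$ratio[2], 1, tolerance = 1e-12)
})

test_that("a single-dependency network ranks its only used input first", {
  f <- fit_small(7, target_fun = function(x) ifelse(x[, 3] > 3, 2L, 1L),
                 epochs = 800)
  sr <- sensitivity_ratios(f$fit, f$x, f$y)
  expect_equal(sr$rank[3], 1L)
  expect_equal(sort(sr$rank), 1:5)
})

test_that("ratios match a naive re-evaluation with the input fixed at its mean", {
  for (s in 1:5) {
    f <- fit_small(s + 20, n = 25, epochs = 150)
    sr <- sensitivity_ratios(f$fit, f$x, f$y)
    xs <- scale(f$x, center = f$fit$center, scale = f$fit$scale)
    tg <- diag(f$fit$spec$n_classes)[f$y, ]
    base <- driverisk:::network_loss_grad(f$fit, xs, tg, grad = FALSE)$loss
    for (j in 1:5) {
      xj <- f$x
      xj[, j] <- f$fit$center[j]  # raw-scale mean substitution
      xjs <- scale(xj, center = f$fit$center, scale = f$fit$scale)
      lj <- driverisk:::network_loss_grad(f$fit, xjs, tg, grad = FALSE)$loss
      expect_equal(sr$ratio[j], lj / base, tolerance = 1e-10)
    }
  }
})

test_that("ratios are invariant to reordering training rows", {
  f <- fit_small(33, n = 30, epochs = 100)
  sr1 <- sensitivity_ratios(f$fit, f$x, f$y)
  perm <- sample(30)
  sr2 <- sensitivity_ratios(f$fit, f$x[perm, ], f$y[perm])
  expect_equal(sr1$ratio, sr2$ratio, tolerance = 1e-12)
})

test_that("in the linear limit, ratio ordering follows |weight| x input spread", {
  # one hidden unit per input with tiny input weights keeps the logistic in
  # its linear range, so the network computes ~ sum_j w_j x_j in closed form
  w <- c(0.6, 0.05, 0.3, 0.01, 0.15)
  a <- 0.01
  p <- list(w_ih = diag(rep(a, 5)), theta_h = rep(0, 5),
            w_hj = matrix(4 * w / a, 5, 1), theta_j = sum(2 * w / a),
            task = "regression", center = rep(0, 5), scale = rep(1, 5),
            spec = model_spec(7))
  class(p) <- "network_params"
  set.seed(9)
  x <- matrix(rnorm(400 * 5), 400, 5)
  y <- as.numeric(x %*% w)  # the exact linear target
  sr <- sensitivity_ratios(p, x, y)
  # substituting input j costs ~ w_j^2 Var(x_j): ranks follow |w_j| sd_j
  expect_equal(order(-sr$ratio), order(-abs(w)))
})

test_that("zero original error reports infinite ratios with a warning", {
  p <- list(w_ih = matrix(0, 5, 2), theta_h = rep(0, 2),
            w_hj = matrix(0, 2, 1), theta_j = 0,
            task = "regression", center = rep(0, 5), scale = rep(1, 5),
            spec = model_spec(7))
  class(p) <- "network_params"
  x <- matrix(rnorm(20), 4, 5)
  expect_warning(sr <- sensitivity_ratios(p, x, rep(0, 4)), "zero")
  expect_true(all(is.infinite(sr$ratio)))
})

test_that("Spearman rho hits the exact extremes and matches a naive rank formula", {
  x <- c(2, 5, 1, 4, 3)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  set.seed(12)
  for (rep in 1:20) {
    a <- sample(1:6, 15, TRUE)  # heavy ties
    b <- sample(1:6, 15, TRUE)
    got <- spearman_rho(a, b)
    ra <- rank(a); rb <- rank(b)  # average ranks for ties
    r_hand <- sum((ra - mean(ra)) * (rb - mean(rb))) /
      sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
    expect_equal(got$rho, r_hand, tolerance = 1e-12)
  }
  expect_equal(spearman_rho(rep(2, 5), 1:5)$flag, "undefined")
  expect_error(spearman_rho(1:3, 1:3), "n >= 4")
})

test_that("dropping a no-signal factor barely moves accuracy; dropping the only signal hurts", {
  cfg <- cohort_config(n_drivers = 120, seed = 314, dispersion = rep(0.02, 6))
  L <- matrix(0, 6, 5)
  L[5, 4] <- 1.8  # only neuroticism drives excessive rotation speed
  cfg$loading_matrix <- L
  null_deltas <- numeric(8)
  signal_deltas <- numeric(8)
  for (s in 1:8) {
    cc <- cfg; cc$seed <- 2000 + s
    coh <- generate_cohort(cc)
    sch <- build_scheme(coh$counts)
    hyper <- train_config(max_epochs = 800)
    null_ab <- ablation_compare(model_spec(5), coh$traits, sch$profiles,
                                "agreeableness", n_experiments = 2,
                                seeds = c(s, s + 50), hyper = hyper)
    sig_ab <- ablation_compare(model_spec(5), coh$traits, sch$profiles,
                               "neuroticism", n_experiments = 2,
                               seeds = c(s, s + 50), hyper = hyper)
    null_deltas[s] <- null_ab$delta["accuracy"]
    signal_deltas[s] <- sig_ab$delta["accuracy"]
  }
  expect_lt(abs(mean(null_deltas)), 5)
  expect_lt(mean(signal_deltas), 0)
  expect_lt(mean(signal_deltas), mean(null_deltas))
})
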