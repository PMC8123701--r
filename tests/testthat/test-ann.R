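random_params <- function(seed, d = 5, H = 6, K = 4, task = "classification") {
  set.seed(seed)
  list(w_ih = matrix(rnorm(d * H), d, H), theta_h = rnorm(H),
       w_hj = matrix(rnorm(H * K), H, K), theta_j = rnorm(K), task = task)
}

test_that("the forward pass matches a naive per-unit evaluator", {
  for (s in 1:20) {
    task <- if (s %% 2) "classification" else "regression"
    p <- random_params(s, K = if (task == "classification") 4 else 1, task = task)
    x <- rnorm(5)
    expect_equal(as.numeric(forward_pass(p, x)), naive_forward(p, x),
                 tolerance = 1e-10)
  }
})

test_that("a hand-built one-hidden-unit network evaluates to the hand-computed value", {
  p <- list(w_ih = matrix(c(0.5, -0.2, 0.1, 0.3, -0.4), 5, 1),
            theta_h = 0.2, w_hj = matrix(2, 1, 1), theta_j = -0.5,
            task = "regression")
  x <- c(3, 2, 4, 1, 5)
  a <- 0.5 * 3 - 0.2 * 2 + 0.1 * 4 + 0.3 * 1 - 0.4 * 5 - 0.2
  hand <- 2 * (1 / (1 + exp(-a))) + 0.5
  expect_equal(as.numeric(forward_pass(p, x)), hand, tolerance = 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  for (task in c("classification", "regression")) {
    K <- if (task == "classification") 3 else 1
    p <- random_params(42, H = 4, K = K, task = task)
    set.seed(43)
    n <- 8
    x <- matrix(rnorm(n * 5), n, 5)
    tg <- if (task == "classification") diag(K)[sample(K, n, TRUE), ]
          else matrix(rnorm(n), ncol = 1)
    g <- driverisk:::network_loss_grad(p, x, tg)
    eps <- 1e-6
    for (nm in c("w_ih", "theta_h", "w_hj", "theta_j")) {
      for (i in seq_along(p[[nm]])) {
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (driverisk:::network_loss_grad(pp, x, tg, grad = FALSE)$loss -
               driverisk:::network_loss_grad(pm, x, tg, grad = FALSE)$loss) / (2 * eps)
        denom <- max(abs(fd), abs(g[[nm]][i]), 1e-8)
        expect_lt(abs(fd - g[[nm]][i]) / denom, 1e-5)
      }
    }
  }
})

test_that("training separates a linearly separable toy problem", {
  set.seed(5)
  x <- matrix(runif(300, 1, 5), 60, 5)
  y <- ifelse(x[, 1] > 3, 2L, 1L)
  spec <- model_spec(1); spec$n_classes <- 2
  fit <- train_network(spec, x, y, train_config(max_epochs = 500, seed = 1))
  expect_equal(accuracy(y, predict(fit, x)), 100)
})

test_that("training is deterministic given the seed and loss is non-increasing under a small step", {
  set.seed(10)
  x <- matrix(runif(150, 1, 5), 30, 5)
  y <- sample(1:4, 30, TRUE)
  spec <- model_spec(2)
  f1 <- train_network(spec, x, y, train_config(seed = 3, max_epochs = 200))
  f2 <- train_network(spec, x, y, train_config(seed = 3, max_epochs = 200))
  expect_identical(f1$w_ih, f2$w_ih)
  expect_identical(predict(f1, x), predict(f2, x))

  # plain gradient descent with a tiny step: epoch losses never increase
  p <- random_params(77, K = 4)
  xs <- scale(x)
  tg <- diag(4)[y, ]
  losses <- numeric(60)
  for (e in 1:60) {
    g <- driverisk:::network_loss_grad(p, xs, tg)
    losses[e] <- g$loss
    for (nm in c("w_ih", "theta_h", "w_hj", "theta_j"))
      p[[nm]] <- p[[nm]] - 0.01 * g[[nm]]
  }
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("a symmetric zero network ties all classes and argmax breaks to the lowest", {
  p <- list(w_ih = matrix(0, 5, 4), theta_h = rep(0, 4),
            w_hj = matrix(0, 4, 3), theta_j = rep(0, 3),
            task = "classification", center = rep(0, 5), scale = rep(1, 5),
            spec = model_spec(1))
  class(p) <- "network_params"
  probs <- forward_pass(p, matrix(rnorm(10), 2, 5))
  expect_true(all(abs(probs - 1 / 3) < 1e-12))
  expect_equal(predict(p, matrix(3, 2, 5)), c(1L, 1L))
})

test_that("regression predictions clamp and round for reporting", {
  spec <- model_spec(7)
  p <- list(w_ih = matrix(0, 5, 2), theta_h = rep(0, 2),
            w_hj = matrix(0, 2, 1), theta_j = -3.2,  # output always 3.2
            task = "regression", center = rep(3, 5), scale = rep(1, 5),
            spec = spec)
  class(p) <- "network_params"
  expect_equal(predict(p, matrix(3, 1, 5)), 3.2)
  expect_equal(predict(p, matrix(3, 1, 5), type = "reported"), 6L)
  p$theta_j <- -30.7
  expect_equal(predict(p, matrix(3, 1, 5), type = "reported"), 24L)
})

test_that("inputs beyond the Likert scale warn but still predict", {
  set.seed(2)
  x <- matrix(runif(100, 1, 5), 20, 5)
  y <- sample(1:4, 20, TRUE)
  fit <- train_network(model_spec(3), x, y, train_config(max_epochs = 50, seed = 1))
  expect_warning(predict(fit, matrix(6, 1, 5)), "extrapolat")
})

test_that("stratified split takes ceil(3/4) per stratum and sends singletons to training", {
  labels <- rep(1:4, times = c(15, 16, 6, 3))
  sp <- stratified_split(labels, 0.75, seed = 1)
  tr_sizes <- as.numeric(table(labels[sp$train]))
  expect_equal(tr_sizes, c(12, 12, 5, 3))
  expect_equal(length(sp$train) + length(sp$test), 40)
  expect_equal(length(intersect(sp$train, sp$test)), 0)

  single <- stratified_split(c(1, 1, 1, 2), 0.75, seed = 1)
  expect_true(4 %in% single$train)

  sp2 <- stratified_split(labels, 0.75, seed = 2)
  expect_false(identical(sp$test, sp2$test))
  expect_equal(as.numeric(table(labels[sp2$train])), tr_sizes)
})

test_that("shuffled labels give no edge over the majority class on held-out data", {
  set.seed(123)
  x <- matrix(runif(400 * 5, 1, 5), 400, 5)
  diffs <- numeric(12)
  for (s in 1:12) {
    set.seed(1000 + s)
    y <- sample(1:4, 400, TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    sp <- stratified_split(y, 0.75, seed = s)
    fit <- train_network(model_spec(1), x[sp$train, ], y[sp$train],
                         train_config(max_epochs = 400, seed = s))
    pred <- predict(fit, x[sp$test, ])
    maj <- as.integer(names(which.max(table(y[sp$train]))))
    diffs[s] <- mean(pred == y[sp$test]) - mean(maj == y[sp$test])
  }
  # mean difference statistically indistinguishable from zero
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("experiment reports average the per-experiment metrics", {
  set.seed(3)
  cfg <- fleet_like_config(n_drivers = 60, seed = 31)
  coh <- generate_cohort(cfg)
  sch <- build_scheme(coh$counts)
  rep4 <- run_experiments(model_spec(5), coh$traits, sch$profiles,
                          n_experiments = 2, seeds = c(1, 2),
                          hyper = train_config(max_epochs = 300))
  expect_equal(nrow(rep4$per_experiment), 2)
  expect_equal(unname(rep4$average["accuracy"]),
               mean(rep4$per_experiment$accuracy))
  rep1 <- run_experiments(model_spec(5), coh$traits, sch$profiles,
                          n_experiments = 1, seeds = 7,
                          hyper = train_config(max_epochs = 300))
  expect_equal(unname(rep1$average["accuracy"]),
               rep1$per_experiment$accuracy[1])
})

test_that("trained networks survive a JSON round trip", {
  set.seed(8)
  x <- matrix(runif(100, 1, 5), 20, 5)
  colnames(x) <- trait_names_for_test()
  y <- sample(1:4, 20, TRUE)
  fit <- train_network(model_spec(6), x, y, train_config(max_epochs = 100, seed = 2))
  path <- tempfile(fileext = ".json")
  save_network(fit, path)
  back <- load_network(path)
  expect_equal(back$w_ih, fit$w_ih, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(predict(back, x), predict(fit, x))
})
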