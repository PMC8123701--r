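#' Model roster for trait-based behavior and risk prediction
#'
#' Eight models share the five trait means as inputs. Models 1-6 classify the
#' driver's class (1..4) for one aberrant behavior each, in canonical behavior
#' order; Model 7 regresses the driving-risk index (integer, reported clamped
#' to [6, 24] for a 4-class scheme); Model 8 classifies the driving-risk
#' level (1..5).
#'
#' @param model_id Integer 1..8.
#' @param k_behavior,k_risk Class counts of the underlying scheme.
#' @return List of class `model_spec` with `model_id`, `target` (column name
#'   in a scheme's profiles), `task` (`"classification"` or `"regression"`),
#'   and `n_classes` (NA for regression).
#' @export
model_spec <- function(model_id, k_behavior = 4, k_risk = 5) {
  if (!model_id %in% 1:8) stop_input("model_id must be 1..8")
  bn <- behavior_names()
  if (model_id <= 6) {
    out <- list(model_id = model_id, target = bn[model_id],
                task = "classification", n_classes = k_behavior)
  } else if (model_id == 7) {
    out <- list(model_id = 7, target = "risk_index", task = "regression",
                n_classes = NA_integer_, clamp = c(6L, 6L * k_behavior))
  } else {
    out <- list(model_id = 8, target = "risk_level",
                task = "classification", n_classes = k_risk)
  }
  structure(out, class = "model_spec")
}

#' Training hyperparameters for the feed-forward network
#'
#' @param hidden_size Hidden units (default 8).
#' @param learning_rate Full-batch gradient-descent step (default 0.05).
#' @param momentum Momentum coefficient (default 0.9).
#' @param max_epochs Epoch cap (default 5000).
#' @param tol Stop when the epoch-over-epoch loss change drops below this
#'   (default 1e-6).
#' @param seed Seed for weight initialization.
#' @return List of class `train_config`.
#' @export
train_config <- function(hidden_size = 8, learning_rate = 0.05, momentum = 0.9,
                         max_epochs = 5000, tol = 1e-6, seed = 1) {
  structure(list(hidden_size = hidden_size, learning_rate = learning_rate,
                 momentum = momentum, max_epochs = max_epochs, tol = tol,
                 seed = as.integer(seed)),
            class = "train_config")
}

logistic <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the single-hidden-layer network
#'
#' Computes y = g(W_hj' f(W_ih' x - theta_h) - theta_j): a logistic hidden
#' layer with subtractive thresholds, then either a softmax (classification)
#' or identity (regression) output layer, also with subtractive thresholds.
#'
#' @param params Network parameters (a `network_params` object or a list with
#'   `w_ih` (d x H), `theta_h` (H), `w_hj` (H x K), `theta_j` (K), `task`).
#' @param x Input matrix (n x d) on the scale the network was trained on;
#'   a single input vector is accepted.
#' @return n x K matrix of outputs (class probabilities, or the regression
#'   value with K = 1).
#' @export
forward_pass <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  hidden <- logistic(sweep(x %*% params$w_ih, 2, params$theta_h))
  out <- sweep(hidden %*% params$w_hj, 2, params$theta_j)
  if (identical(params$task, "classification")) {
    z <- out - apply(out, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    out
  }
}

# Loss and analytic gradients of the network on (X, target). Classification:
# mean cross-entropy against one-hot Y; regression: mean squared error.
# Softmax+CE and identity+SE share the output delta (pred - target).
network_loss_grad <- function(params, x, target, grad = TRUE) {
  n <- nrow(x)
  hidden <- logistic(sweep(x %*% params$w_ih, 2, params$theta_h))
  out <- sweep(hidden %*% params$w_hj, 2, params$theta_j)
  if (identical(params$task, "classification")) {
    z <- out - apply(out, 1, max)
    p <- exp(z) / rowSums(exp(z))
    loss <- -mean(log(pmax(rowSums(p * target), 1e-12)))
    delta <- (p - target) / n
  } else {
    loss <- mean((out - target)^2)
    delta <- 2 * (out - target) / n
  }
  if (!grad) return(list(loss = loss))
  g_whj <- t(hidden) %*% delta
  g_thj <- -colSums(delta)
  dh <- (delta %*% t(params$w_hj)) * hidden * (1 - hidden)
  g_wih <- t(x) %*% dh
  g_thh <- -colSums(dh)
  list(loss = loss, w_ih = g_wih, theta_h = g_thh, w_hj = g_whj, theta_j = g_thj)
}

#' Train a trait-to-class (or trait-to-index) network
#'
#' Full-batch gradient descent with momentum on a single-hidden-layer
#' network: logistic hidden units, softmax output with cross-entropy loss for
#' classification, identity output with squared-error loss for regression.
#' Inputs are standardized by the training-set mean and SD (stored in the
#' returned object and reapplied at prediction time). Deterministic given the
#' config seed.
#'
#' @param spec A [model_spec()].
#' @param x Training inputs: n x d matrix or data frame (default layout: the
#'   five trait columns).
#' @param y Training targets: integer class labels (classification) or reals
#'   (regression).
#' @param hyper A [train_config()].
#' @return Object of class `network_params`: weights/thresholds, transfer
#'   functions, the input scaler, loss trace summary, and the spec.
#' @export
train_network <- function(spec, x, y, hyper = train_config()) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_input("need at least 2 training examples")
  if (nrow(x) != length(y)) stop_input("x and y sizes differ")
  d <- ncol(x); H <- hyper$hidden_size
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  if (spec$task == "classification") {
    K <- spec$n_classes
    if (!all(y %in% seq_len(K))) stop_input("class labels must be in 1..%d", K)
    target <- diag(K)[y, , drop = FALSE]
  } else {
    K <- 1L
    target <- matrix(as.numeric(y), ncol = 1)
  }

  params <- with_seed(hyper$seed, list(
    w_ih = matrix(stats::rnorm(d * H, 0, 0.3), d, H),
    theta_h = stats::rnorm(H, 0, 0.3),
    w_hj = matrix(stats::rnorm(H * K, 0, 0.3), H, K),
    theta_j = stats::rnorm(K, 0, 0.3),
    task = spec$task))

  vel <- list(w_ih = params$w_ih * 0, theta_h = params$theta_h * 0,
              w_hj = params$w_hj * 0, theta_j = params$theta_j * 0)
  prev <- Inf; epochs <- 0L; loss <- NA_real_
  for (e in seq_len(hyper$max_epochs)) {
    g <- network_loss_grad(params, xs, target)
    loss <- g$loss
    if (!is.finite(loss))
      stop_input("training diverged (non-finite loss); lower learning_rate = %g",
                 hyper$learning_rate)
    for (nm in c("w_ih", "theta_h", "w_hj", "theta_j")) {
      vel[[nm]] <- hyper$momentum * vel[[nm]] - hyper$learning_rate * g[[nm]]
      params[[nm]] <- params[[nm]] + vel[[nm]]
    }
    epochs <- e
    if (abs(prev - loss) < hyper$tol) break
    prev <- loss
  }
  structure(c(params,
              list(center = ctr, scale = scl, spec = spec, hyper = hyper,
                   final_loss = loss, epochs = epochs)),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("Trained network (model %d, %s): %d -> %d -> %d, loss %.4g after %d epochs\n",
              x$spec$model_id, x$task, nrow(x$w_ih), ncol(x$w_ih), ncol(x$w_hj),
              x$final_loss, x$epochs))
  invisible(x)
}

#' Predict from a trained network
#'
#' Classification returns the argmax class (ties broken toward the lowest
#' class index). Regression returns the raw network output by default, or
#' the reporting value (rounded half-up and clamped to the feasible index
#' range) with `type = "reported"`. Inputs outside the Likert range [1, 5]
#' trigger a warning (extrapolation) but are accepted.
#'
#' @param object A `network_params` object.
#' @param newdata Matrix/data frame of trait inputs (raw scale).
#' @param type `"class"` (default for classification), `"raw"`, or
#'   `"reported"` (regression display value).
#' @param ... Unused.
#' @return Integer classes, raw outputs, or reported integers.
#' @export
predict.network_params <- function(object, newdata,
                                   type = c("auto", "class", "raw", "reported"),
                                   ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (any(x < 1 | x > 5))
    warning("inputs outside [1, 5]; extrapolating beyond the trait scale")
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  out <- forward_pass(object, xs)
  if (object$task == "classification") {
    if (type == "raw") return(out)
    return(max.col(out, ties.method = "first"))
  }
  v <- as.numeric(out)
  if (type == "reported") {
    cl <- object$spec$clamp
    return(as.integer(pmin(cl[2], pmax(cl[1], round_half_up(v)))))
  }
  if (type == "class") stop_input("type = 'class' is undefined for regression")
  v
}

#' Stratified train/test split
#'
#' Per stratum, `ceil(fraction * n_s)` members go to training; singleton
#' strata go entirely to training so every observed class is represented.
#' Deterministic given the seed; different seeds change memberships but not
#' per-stratum counts.
#'
#' @param labels Stratum label per observation.
#' @param fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List of class `split_plan` with integer index vectors `train` and
#'   `test`.
#' @export
stratified_split <- function(labels, fraction = 0.75, seed = 1) {
  if (length(labels) == 0) stop_input("empty cohort")
  if (fraction <= 0 || fraction >= 1) stop_input("'fraction' must be in (0, 1)")
  train <- integer(0)
  with_seed(seed, {
    for (s in unique(labels)) {
      idx <- which(labels == s)
      n_tr <- ceiling(fraction * length(idx))
      pick <- if (length(idx) == 1) idx else sample(idx, n_tr)
      train <- c(train, pick)
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_along(labels), train)),
            class = "split_plan")
}

#' Run the repeated stratified-split experiment protocol
#'
#' Repeats the study protocol: split the cohort 75/25 stratified on the
#' target class (risk level for the index-regression model), train on the
#' training portion, evaluate on the held-out portion. Classification models
#' report accuracy per experiment; the regression model reports MAPE and R^2
#' computed on the reported (integer, clamped) predictions.
#'
#' @param spec A [model_spec()].
#' @param traits Data frame/matrix of the five trait columns.
#' @param profiles Data frame of cohort risk profiles (from
#'   [build_scheme()]`$profiles`), supplying the target and, for Model 7, the
#'   `risk_level` stratification labels.
#' @param n_experiments Number of repeats (default 4).
#' @param seeds Split/initialization seeds, one per experiment (default
#'   `1:n_experiments`).
#' @param hyper A [train_config()].
#' @param input_cols Trait columns to use (default all five; drop one for
#'   ablation runs).
#' @return Object of class `experiment_report`: data frame `per_experiment`,
#'   named `average` vector, and the spec.
#' @export
run_experiments <- function(spec, traits, profiles,
                            n_experiments = 4, seeds = seq_len(n_experiments),
                            hyper = train_config(), input_cols = trait_names()) {
  if (n_experiments < 1) stop_input("n_experiments must be >= 1")
  if (length(seeds) != n_experiments) stop_input("need one seed per experiment")
  x <- as.matrix(as.data.frame(traits)[input_cols])
  y <- profiles[[spec$target]]
  strata <- if (spec$task == "regression") profiles$risk_level else y
  if (is.null(strata)) strata <- y
  rows <- lapply(seq_len(n_experiments), function(i) {
    sp <- stratified_split(strata, 0.75, seed = seeds[i])
    h <- hyper; h$seed <- seeds[i]
    fit <- train_network(spec, x[sp$train, , drop = FALSE], y[sp$train], h)
    if (length(sp$test) == 0)
      stop_input("empty test set; cohort too small for the split")
    if (spec$task == "classification") {
      pred <- predict(fit, x[sp$test, , drop = FALSE])
      data.frame(experiment = i, seed = seeds[i], n_test = length(sp$test),
                 accuracy = accuracy(y[sp$test], pred))
    } else {
      pred <- predict(fit, x[sp$test, , drop = FALSE], type = "reported")
      data.frame(experiment = i, seed = seeds[i], n_test = length(sp$test),
                 mape = mape(y[sp$test], pred),
                 r_squared = r_squared(y[sp$test], pred))
    }
  })
  per <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per), c("experiment", "seed", "n_test"))
  avg <- vapply(per[metric_cols], mean, numeric(1))
  structure(list(spec = spec, per_experiment = per, average = avg,
                 input_cols = input_cols),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Model %d (%s -> %s), %d experiments:\n", x$spec$model_id,
              paste(x$input_cols, collapse = "+"), x$spec$target,
              nrow(x$per_experiment)))
  print(x$per_experiment, row.names = FALSE)
  cat("Average:", paste(sprintf("%s = %.3f", names(x$average), x$average),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Persist / restore trained network parameters as JSON
#'
#' @param params A `network_params` object.
#' @param path Output file.
#' @return `save_network` invisibly returns `path`; `load_network` returns
#'   the restored `network_params`.
#' @export
save_network <- function(params, path) {
  obj <- lapply(unclass(params), function(el)
    if (inherits(el, "model_spec") || inherits(el, "train_config"))
      unclass(el) else el)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("w_ih", "w_hj")) obj[[nm]] <- as.matrix(obj[[nm]])
  obj$spec <- structure(obj$spec, class = "model_spec")
  obj$hyper <- structure(obj$hyper, class = "train_config")
  structure(obj, class = "network_params")
}
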