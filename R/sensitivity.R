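#' Mean-substitution sensitivity ratios of a trained network
#'
#' For each input in turn, every training row's value for that input is
#' replaced by the training-sample mean (0 on the standardized scale the
#' network trains on), the network error — the same loss used in training —
#' is recomputed on the training set, and the ratio to the unperturbed error
#' is reported. A ratio near 1 means the input carries no usable signal; the
#' larger the ratio, the more the model leans on that input. Rank 1 is the
#' largest ratio; ties break toward the lower input index.
#'
#' @param params A trained `network_params`.
#' @param x Training inputs (raw scale), n x d with n >= 2.
#' @param y Training targets as passed to [train_network()].
#' @return Data frame with `input`, `ratio`, `rank`. If the original error is
#'   zero, ratios are reported as `Inf` with a warning.
#' @export
sensitivity_ratios <- function(params, x, y) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_input("need at least 2 training rows")
  xs <- sweep(sweep(x, 2, params$center), 2, params$scale, "/")
  target <- if (params$task == "classification")
    diag(params$spec$n_classes)[y, , drop = FALSE]
  else matrix(as.numeric(y), ncol = 1)
  base <- network_loss_grad(params, xs, target, grad = FALSE)$loss
  d <- ncol(xs)
  sub_loss <- vapply(seq_len(d), function(j) {
    xj <- xs
    xj[, j] <- 0  # the training mean on the standardized scale
    network_loss_grad(params, xj, target, grad = FALSE)$loss
  }, numeric(1))
  if (base == 0) {
    warning("original training error is zero; ratios reported as Inf")
    ratio <- rep(Inf, d)
  } else {
    ratio <- sub_loss / base
  }
  rk <- integer(d)
  rk[order(-ratio, seq_len(d))] <- seq_len(d)
  data.frame(input = colnames(x) %||% paste0("x", seq_len(d)),
             ratio = ratio, rank = rk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spearman rank correlation with a t-approximation significance test
#'
#' Rank correlation using average ranks for ties, with a two-tailed
#' significance flag at the 95% (`*`) and 99% (`**`) confidence levels from
#' the t approximation. Constant inputs yield an NA rho flagged undefined.
#'
#' @param x,y Equal-length numeric vectors, n >= 4.
#' @return List with `rho`, `p`, `flag` ("", "*", "**"), `n`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 4) stop_input("need equal-length vectors, n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, flag = "undefined", n = n))
  rho <- stats::cor(x, y, method = "spearman")
  p <- cor_p_value(rho, n)
  list(rho = rho, p = p, flag = sig_flag(p), n = n)
}

#' Sensitivity table across the five personality traits for one model
#'
#' Runs the experiment protocol, then averages each trait's mean-substitution
#' ratio across the per-experiment trained networks, and adds the Spearman
#' correlation of each trait with the model target over the full cohort —
#' ratio magnitude says how much the model uses a trait; the rank correlation
#' says in which direction the trait moves the target.
#'
#' @inheritParams run_experiments
#' @return Data frame with `input`, `avg_ratio`, `rank`, `spearman_rho`,
#'   `significance`.
#' @export
sensitivity_table <- function(spec, traits, profiles, n_experiments = 4,
                              seeds = seq_len(n_experiments),
                              hyper = train_config()) {
  x <- as.matrix(as.data.frame(traits)[trait_names()])
  y <- profiles[[spec$target]]
  strata <- if (spec$task == "regression") profiles$risk_level else y
  ratios <- matrix(NA_real_, n_experiments, 5)
  for (i in seq_len(n_experiments)) {
    sp <- stratified_split(strata, 0.75, seed = seeds[i])
    h <- hyper; h$seed <- seeds[i]
    fit <- train_network(spec, x[sp$train, , drop = FALSE], y[sp$train], h)
    ratios[i, ] <- sensitivity_ratios(fit, x[sp$train, , drop = FALSE],
                                      y[sp$train])$ratio
  }
  avg <- colMeans(ratios)
  rk <- integer(5); rk[order(-avg, 1:5)] <- 1:5
  sr <- lapply(1:5, function(j) spearman_rho(x[, j], y))
  data.frame(input = trait_names(), avg_ratio = avg, rank = rk,
             spearman_rho = vapply(sr, `[[`, numeric(1), "rho"),
             significance = vapply(sr, `[[`, character(1), "flag"))
}

#' Leave-one-factor-out ablation of a prediction model
#'
#' Repeats the experiment protocol twice on identical splits and seeds — once
#' with all five traits, once without `drop_factor` — and reports the paired
#' per-experiment performance and the difference (ablated minus full). For
#' classification the metric is accuracy; for the index-regression model the
#' deltas cover MAPE and R^2.
#'
#' @inheritParams run_experiments
#' @param drop_factor One of the five trait names to exclude.
#' @return List of class `ablation_report` with `full`, `ablated`
#'   (experiment reports), and `delta` (named average differences,
#'   ablated - full).
#' @export
ablation_compare <- function(spec, traits, profiles, drop_factor,
                             n_experiments = 4, seeds = seq_len(n_experiments),
                             hyper = train_config()) {
  if (!drop_factor %in% trait_names())
    stop_input("'drop_factor' must be one of: %s",
               paste(trait_names(), collapse = ", "))
  full <- run_experiments(spec, traits, profiles, n_experiments, seeds, hyper)
  abl <- run_experiments(spec, traits, profiles, n_experiments, seeds, hyper,
                         input_cols = setdiff(trait_names(), drop_factor))
  structure(list(drop_factor = drop_factor, full = full, ablated = abl,
                 delta = abl$average - full$average),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat(sprintf("Ablation of '%s' (model %d):\n", x$drop_factor,
              x$full$spec$model_id))
  cat("Average delta (ablated - full):",
      paste(sprintf("%s = %+.3f", names(x$delta), x$delta), collapse = ", "),
      "\n")
  invisible(x)
}
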