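# Independent oracles used across the suite. Each is deliberately written as
# naive, direct code so it shares nothing with the implementation it checks.

# Exhaustive enumeration of all contiguous k-partitions of a sorted sample;
# returns the minimal sum of within-class squared deviations.
enumerate_min_sdcm <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  if (k == 1) return(sum((v - mean(v))^2))
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (ci in seq_len(ncol(cuts))) {
    ends <- c(cuts[, ci], n)
    starts <- c(1, head(ends, -1) + 1)
    s <- 0
    for (g in seq_len(k)) {
      seg <- v[starts[g]:ends[g]]
      s <- s + sum((seg - mean(seg))^2)
    }
    best <- min(best, s)
  }
  best
}

# Naive double-loop variance decomposition for a class assignment.
naive_decomposition <- function(values, assignment) {
  grand <- sum(values) / length(values)
  sdam <- 0
  for (v in values) sdam <- sdam + (v - grand)^2
  sdcm <- 0
  for (cl in unique(assignment)) {
    seg <- values[assignment == cl]
    mu <- sum(seg) / length(seg)
    for (v in seg) sdcm <- sdcm + (v - mu)^2
  }
  list(sdam = sdam, sdcm = sdcm, sdbc = sdam - sdcm)
}

# Single-pass reference event detector, coded independently of detect_events:
# explicit per-sample state machines instead of rle-based episode extraction.
reference_detector_counts <- function(trace, rules = rule_config()) {
  sp <- trace$speed_kmh; rpm <- trace$rpm
  n <- nrow(trace)
  counts <- setNames(numeric(6),
                     c("exceeding_speed_limit", "abnormal_stay",
                       "hard_acceleration", "driving_overtime",
                       "excessive_rotation_speed", "hard_deceleration"))
  count_runs <- function(flag, min_len, strict_gt = TRUE) {
    total <- 0; run <- 0
    for (i in seq_along(flag)) {
      if (flag[i]) run <- run + 1
      if (!flag[i] || i == length(flag)) {
        ok <- if (strict_gt) run > min_len else run >= min_len
        if (ok) total <- total + 1
        if (!flag[i]) run <- 0
      }
    }
    total
  }
  counts["exceeding_speed_limit"] <-
    count_runs(sp > rules$speed_limit_kmh, rules$speeding_min_s)
  counts["driving_overtime"] <- count_runs(sp > 0, rules$overtime_max_s)
  counts["excessive_rotation_speed"] <-
    count_runs(sp < rules$rotation_speed_kmh & rpm > rules$rotation_rpm,
               rules$rotation_consec_s, strict_gt = FALSE)
  # hard deceleration on per-second drops
  if (n >= 2) {
    drops <- sp[-n] - sp[-1] > rules$decel_drop_kmh
    counts["hard_deceleration"] <-
      count_runs(drops, rules$decel_consec_s, strict_gt = FALSE)
  }
  # hard acceleration: merged 5-s windows
  if (n >= 5) {
    covered <- rep(FALSE, n)
    for (t in 1:(n - 4))
      if (sp[t + 4] - sp[t] > rules$accel_diff_kmh) covered[t:(t + 4)] <- TRUE
    counts["hard_acceleration"] <- count_runs(covered, 1, strict_gt = FALSE)
  }
  # abnormal stay: slow runs, long enough, spatially confined
  run_start <- NA
  stay <- 0
  for (i in seq_len(n + 1)) {
    slow <- i <= n && sp[i] < rules$stay_speed_kmh
    if (slow && is.na(run_start)) run_start <- i
    if (!slow && !is.na(run_start)) {
      idx <- run_start:(i - 1)
      if (length(idx) > rules$stay_min_s) {
        dmax <- 0
        for (a in idx) for (b in idx) {
          dd <- sqrt((trace$x_m[a] - trace$x_m[b])^2 +
                       (trace$y_m[a] - trace$y_m[b])^2)
          if (dd > dmax) dmax <- dd
        }
        if (dmax < rules$stay_range_m) stay <- stay + 1
      }
      run_start <- NA
    }
  }
  counts["abnormal_stay"] <- stay
  counts
}

# Random telemetry trace with occasional rule-violating stretches.
random_trace <- function(seed, duration_s = 420) {
  set.seed(seed)
  sp <- numeric(duration_s); rpm <- numeric(duration_s)
  t <- 1
  while (t <= duration_s) {
    mode <- sample(c("cruise", "fast", "slow", "surge", "brake", "rev"), 1,
                   prob = c(0.3, 0.2, 0.15, 0.15, 0.1, 0.1))
    len <- min(sample(3:140, 1), duration_s - t + 1)
    idx <- t:(t + len - 1)
    sp[idx] <- switch(mode,
      cruise = 70 + rnorm(len, 0, 3),
      fast = 92 + rnorm(len, 0, 2),
      slow = runif(len, 0, 4),
      surge = seq(40, 40 + 9 * len, length.out = len),
      brake = pmax(0, 100 - 16 * seq_len(len)),
      rev = 60 + rnorm(len, 0, 2))
    rpm[idx] <- if (mode == "rev") 1600 + rnorm(len, 0, 30) else 1200
    t <- t + len
  }
  sp <- pmax(sp, 0)
  mps <- sp / 3.6
  data.frame(driver_id = "R", timestamp = seq_len(duration_s),
             speed_kmh = sp, rpm = rpm,
             x_m = cumsum(mps), y_m = 0)
}

# Naive evaluator of the layered network equation for a single input vector.
naive_forward <- function(params, x) {
  H <- length(params$theta_h)
  K <- length(params$theta_j)
  hidden <- numeric(H)
  for (h in seq_len(H)) {
    s <- 0
    for (i in seq_along(x)) s <- s + params$w_ih[i, h] * x[i]
    hidden[h] <- 1 / (1 + exp(-(s - params$theta_h[h])))
  }
  out <- numeric(K)
  for (k in seq_len(K)) {
    s <- 0
    for (h in seq_len(H)) s <- s + params$w_hj[h, k] * hidden[h]
    out[k] <- s - params$theta_j[k]
  }
  if (identical(params$task, "classification")) exp(out) / sum(exp(out)) else out
}

trait_names_for_test <- function() {
  c("extraversion", "agreeableness", "conscientiousness", "neuroticism",
    "openness")
}

behavior_names_for_test <- function() {
  c("exceeding_speed_limit", "abnormal_stay", "hard_acceleration",
    "driving_overtime", "excessive_rotation_speed", "hard_deceleration")
}

# Calibrated fleet-like generator config shared by signal-recovery tests:
# loadings hit the published trait-behavior correlation table; low residual
# dispersion so the strongest association (0.835) is attainable.
fleet_like_config <- function(n_drivers = 200, seed = 101) {
  calibrate_to_target_correlations(
    reference_trait_behavior_correlations(),
    cohort_config(n_drivers = n_drivers, seed = seed,
                  dispersion = rep(0.02, 6)))
}
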