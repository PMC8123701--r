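#' Build a driving-risk classification scheme from cohort counts
#'
#' Fits Jenks natural breaks per behavior on the raw window counts (default
#' k = 4 classes), scores every driver with the class ordinal of each
#' behavior, sums the six scores into the additive driving-risk index
#' (range 6 to 6k), and fits Jenks on the indices to define the risk levels
#' (default k = 5). The frozen scheme — per-behavior class boundaries with
#' GVF, plus risk-index thresholds with GVF — is what new drivers are
#' classified against.
#'
#' @param counts Data frame with `driver_id` and the six behavior count
#'   columns (canonical names; see `behavior_names` in the package source),
#'   e.g. the `counts` element of a [generate_cohort()] result.
#' @param k_behavior Classes per behavior (default 4).
#' @param k_risk Risk levels (default 5).
#' @param per_hour Classify per-hour rates instead of raw counts? Requires an
#'   `exposure_hours` column. Default FALSE: boundaries live on the count
#'   scale the reference tables use.
#' @return Object of class `risk_scheme`: per-behavior boundary tables and
#'   GVFs, risk thresholds and GVF, per-class/level driver tallies (with
#'   percentages), and the cohort's risk profiles.
#' @export
build_scheme <- function(counts, k_behavior = 4, k_risk = 5, per_hour = FALSE) {
  bn <- behavior_names()
  if (!all(bn %in% names(counts)))
    stop_input("counts must contain columns: %s", paste(bn, collapse = ", "))
  n <- nrow(counts)
  if (n < 2 * max(k_behavior, k_risk))
    stop_input("need at least %d drivers for k = %d",
               2 * max(k_behavior, k_risk), max(k_behavior, k_risk))
  vals <- as.matrix(counts[bn])
  if (per_hour) {
    if (!"exposure_hours" %in% names(counts))
      stop_input("per_hour = TRUE requires an 'exposure_hours' column")
    vals <- vals / counts$exposure_hours
  }

  # a behavior with fewer distinct values than k gets as many classes as the
  # data support (a constant column collapses to one class)
  behavior_fit <- lapply(bn, function(b)
    fit_breaks(vals[, b], min(k_behavior, length(unique(vals[, b])))))
  names(behavior_fit) <- bn
  classes <- sapply(behavior_fit, function(f) f$class_of)
  risk_index <- as.integer(rowSums(classes))
  risk_fit <- fit_breaks(risk_index, min(k_risk, length(unique(risk_index))))

  class_tally <- sapply(behavior_fit, function(f)
    tabulate(f$class_of, nbins = k_behavior))
  level_tally <- tabulate(risk_fit$class_of, nbins = k_risk)

  profiles <- data.frame(driver_id = counts$driver_id, classes,
                         risk_index = risk_index,
                         risk_level = risk_fit$class_of,
                         check.names = FALSE)
  structure(list(
    k_behavior = k_behavior, k_risk = k_risk, per_hour = per_hour,
    behavior_boundaries = lapply(behavior_fit, `[[`, "boundaries"),
    behavior_gvf = vapply(behavior_fit, `[[`, numeric(1), "gvf"),
    risk_boundaries = risk_fit$boundaries,
    risk_gvf = risk_fit$gvf,
    class_tally = class_tally,
    class_pct = class_tally / n * 100,
    level_tally = level_tally,
    level_pct = level_tally / n * 100,
    n_drivers = n,
    profiles = profiles),
    class = "risk_scheme")
}

#' @export
print.risk_scheme <- function(x, ...) {
  cat(sprintf("Driving-risk scheme: %d drivers, k = %d behavior classes, %d risk levels\n",
              x$n_drivers, x$k_behavior, x$k_risk))
  cat("Behavior GVF:\n"); print(round(x$behavior_gvf, 3))
  cat(sprintf("Risk-index GVF: %.3f; levels (drivers): %s\n", x$risk_gvf,
              paste(x$level_tally, collapse = ", ")))
  invisible(x)
}

# Assign a value to a class given an increasing boundary table (lower/upper per
# class). Upper bounds are inclusive. Values in the gap between two classes go
# to the side of the gap midpoint; values beyond the extremes clamp to 1 / k.
assign_class <- function(value, boundaries) {
  k <- nrow(boundaries)
  if (value <= boundaries$upper[1]) return(1L)
  if (value >= boundaries$lower[k]) return(k)
  for (c in seq_len(k - 1)) {
    if (value >= boundaries$lower[c] && value <= boundaries$upper[c]) return(c)
    gap_lo <- boundaries$upper[c]; gap_hi <- boundaries$lower[c + 1]
    if (value > gap_lo && value < gap_hi)
      return(if (value <= (gap_lo + gap_hi) / 2) c else c + 1L)
  }
  k
}

#' Classify a driver against a frozen risk scheme
#'
#' @param counts Either a named numeric vector of the six behavior counts, or
#'   a one-row data frame with the behavior columns (and optionally
#'   `driver_id`, `exposure_hours`).
#' @param scheme A [build_scheme()] result.
#' @return Object of class `risk_profile`: list with `driver_id`,
#'   `behavior_class` (named integer 6-vector), `risk_index` (their sum) and
#'   `risk_level`.
#' @export
classify_driver <- function(counts, scheme) {
  bn <- behavior_names()
  if (is.data.frame(counts)) {
    id <- if ("driver_id" %in% names(counts)) counts$driver_id[1] else "new"
    v <- as.numeric(counts[1, bn])
  } else {
    id <- "new"
    v <- if (!is.null(names(counts))) as.numeric(counts[bn]) else as.numeric(counts)
  }
  if (length(v) != 6 || anyNA(v)) stop_input("need the six behavior counts")
  if (any(v < 0)) stop_input("behavior counts must be non-negative")
  cls <- vapply(seq_along(bn), function(b)
    assign_class(v[b], scheme$behavior_boundaries[[bn[b]]]), integer(1))
  names(cls) <- bn
  idx <- sum(cls)
  lvl <- assign_class(idx, scheme$risk_boundaries)
  structure(list(driver_id = id, behavior_class = cls,
                 risk_index = as.integer(idx), risk_level = as.integer(lvl)),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf("Driver %s: risk index %d (level %d)\n",
              x$driver_id, x$risk_index, x$risk_level))
  print(x$behavior_class)
  invisible(x)
}

#' Cohort behavior-count summary (total, average, min, max per behavior)
#'
#' The display average is total / n rounded half-up to the nearest integer
#' (the convention of the reference fleet table); the exact mean is kept in
#' `average_raw`.
#'
#' @param counts Data frame with the six behavior count columns.
#' @return Data frame with one row per behavior.
#' @export
cohort_summary <- function(counts) {
  bn <- behavior_names()
  if (!all(bn %in% names(counts))) stop_input("missing behavior columns")
  n <- nrow(counts)
  if (n < 1) stop_input("need at least one driver")
  v <- as.matrix(counts[bn])
  data.frame(behavior = bn,
             total = colSums(v),
             average = round_half_up(colSums(v) / n),
             average_raw = colSums(v) / n,
             min = apply(v, 2, min),
             max = apply(v, 2, max),
             row.names = NULL)
}

# Two-tailed p for a Pearson/Spearman r at sample size n via the t approximation.
cor_p_value <- function(r, n) {
  if (is.na(r) || abs(r) >= 1) return(if (is.na(r)) NA_real_ else 0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

sig_flag <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlation screening of behaviors and traits
#'
#' Pairwise Pearson correlations among the six behaviors and between the five
#' traits and the six behaviors, with two-tailed significance flags at the
#' 95% (`*`) and 99% (`**`) confidence levels. Zero-variance columns yield NA
#' correlations flagged as undefined rather than errors.
#'
#' @param traits Data frame with the five trait columns.
#' @param counts Data frame with the six behavior columns (same row order).
#' @return List with `behavior_behavior` and `trait_behavior`, each a list of
#'   `r` (correlations), `p`, and `flags` matrices.
#' @export
correlation_screen <- function(traits, counts) {
  bn <- behavior_names(); tn <- trait_names()
  n <- nrow(counts)
  if (n < 4) stop_input("need n >= 4 drivers")
  B <- as.matrix(counts[bn]); Tm <- as.matrix(traits[tn])
  suppressWarnings({
    rbb <- stats::cor(B)
    rtb <- stats::cor(Tm, B)
  })
  # zero-variance columns produce NA (undefined), kept as NA
  pbb <- apply(rbb, c(1, 2), cor_p_value, n = n); diag(pbb) <- NA
  ptb <- apply(rtb, c(1, 2), cor_p_value, n = n)
  list(
    behavior_behavior = list(r = rbb, p = pbb,
                             flags = matrix(sig_flag(pbb), 6, 6,
                                            dimnames = dimnames(rbb))),
    trait_behavior = list(r = rtb, p = ptb,
                          flags = matrix(sig_flag(ptb), 5, 6,
                                         dimnames = dimnames(rtb))))
}
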