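#' The 32-item Big Five questionnaire key
#'
#' Loads the packaged item key for the five-dimension driver personality
#' questionnaire: 32 five-point Likert items partitioned 6/8/6/7/5 across
#' extraversion, agreeableness, conscientiousness, neuroticism, and openness
#' to experience. Negatively worded items carry `reverse = TRUE`. The
#' `ref_item_mean` / `ref_item_sd` columns are the published per-item
#' aggregates from the 40-driver fleet survey the key mirrors, kept for
#' validation.
#'
#' @return Data frame with columns `item`, `dimension`, `reverse`,
#'   `ref_item_mean`, `ref_item_sd`.
#' @export
big_five_key <- function() {
  path <- system.file("extdata", "big_five_item_key.csv", package = "driverisk",
                      mustWork = TRUE)
  key <- utils::read.csv(path, stringsAsFactors = FALSE)
  key$dimension <- factor(key$dimension, levels = trait_names())
  key
}

#' Score Likert responses into Big Five trait means
#'
#' Each trait dimension is the arithmetic mean of its item values. With
#' `reverse_code = TRUE`, negatively worded items are flipped (v -> 6 - v)
#' before averaging; the default leaves responses as recorded, which is how
#' the published per-dimension aggregates were formed.
#'
#' @param responses Either a length-32 vector of Likert integers (1-5) for one
#'   respondent, or a data frame / matrix with 32 response columns (one row
#'   per respondent; a `driver_id` column, if present, is carried through).
#' @param key Item key as returned by [big_five_key()].
#' @param reverse_code Flip negatively worded items before averaging?
#' @return For a vector input, a named numeric vector of the five trait means.
#'   For tabular input, a data frame with `driver_id` (if supplied) and one
#'   column per trait.
#' @export
#' @examples
#' score_responses(rep(3, 32))  # midpoint is a fixed point of reverse-coding
score_responses <- function(responses, key = big_five_key(), reverse_code = FALSE) {
  if (nrow(key) != 32 || !all(sort(key$item) == 1:32))
    stop_input("key must cover items 1..32")
  if (is.data.frame(responses) || is.matrix(responses)) {
    df <- as.data.frame(responses)
    id <- NULL
    if ("driver_id" %in% names(df)) {
      id <- df$driver_id
      df <- df[setdiff(names(df), "driver_id")]
    }
    if (ncol(df) != 32) stop_input("expected 32 response columns, got %d", ncol(df))
    scored <- t(apply(as.matrix(df), 1, score_one, key = key,
                      reverse_code = reverse_code))
    out <- as.data.frame(scored)
    names(out) <- trait_names()
    if (!is.null(id)) out <- cbind(data.frame(driver_id = id), out)
    return(out)
  }
  score_one(as.numeric(responses), key, reverse_code)
}

score_one <- function(v, key, reverse_code) {
  if (length(v) != 32) stop_input("expected 32 responses, got %d", length(v))
  bad <- which(!(v %in% 1:5))
  if (length(bad))
    stop_input("responses out of range 1..5 for item(s): %s",
               paste(bad, collapse = ", "))
  v <- v[order(key$item)]  # align positions to item ids 1..32
  key <- key[order(key$item), ]
  if (reverse_code) v[key$reverse] <- 6 - v[key$reverse]
  out <- tapply(v, key$dimension, mean)
  stats::setNames(as.numeric(out[trait_names()]), trait_names())
}

#' Per-dimension mean of published per-item means
#'
#' Collapses a vector of 32 per-item means to the five dimension means by
#' plain averaging within dimension — the arithmetic identity behind the
#' published dimension-level aggregates.
#'
#' @param item_means Numeric vector of 32 item means, positionally aligned to
#'   item ids 1..32 (default: the packaged reference values).
#' @param key Item key as returned by [big_five_key()].
#' @return Named numeric vector of five dimension means.
#' @export
dimension_means_from_item_means <- function(item_means = big_five_key()$ref_item_mean,
                                            key = big_five_key()) {
  if (length(item_means) != 32) stop_input("expected 32 item means")
  out <- tapply(item_means[order(key$item)], key[order(key$item), "dimension"], mean)
  stats::setNames(as.numeric(out[trait_names()]), trait_names())
}

#' Cohort-level trait summary (mean and SD per dimension)
#'
#' @param traits Data frame of trait scores, one row per respondent, with the
#'   five trait columns (as produced by [score_responses()]).
#' @return Data frame with `dimension`, `mean`, `sd` in canonical trait order.
#'   With a single respondent, SDs are reported as 0.
#' @export
dimension_summary <- function(traits) {
  tn <- trait_names()
  if (!all(tn %in% names(traits))) stop_input("missing trait columns")
  if (nrow(traits) < 1) stop_input("need at least one respondent")
  m <- vapply(traits[tn], mean, numeric(1))
  s <- if (nrow(traits) == 1) rep(0, 5) else vapply(traits[tn], stats::sd, numeric(1))
  data.frame(dimension = tn, mean = as.numeric(m), sd = as.numeric(s))
}
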