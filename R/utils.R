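#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for display values in reports where
#' `base::round()`'s round-half-to-even rule would disagree with conventional
#' table formatting (e.g. 72.5 displayed as 73).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(72.5)   # 73
#' round(72.5)           # 72 (banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a private, restorable RNG stream seeded from `seed`.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Canonical aberrant-behavior and personality-trait names
#'
#' Fixed vocabularies used throughout the package: six aberrant driving
#' behaviors (count columns, classification targets) and the five personality
#' dimensions (model inputs), each in its canonical order.
#'
#' @return Character vector of six behavior names or five trait names.
#' @export
behavior_names <- function() {
  c("exceeding_speed_limit", "abnormal_stay", "hard_acceleration",
    "driving_overtime", "excessive_rotation_speed", "hard_deceleration")
}

#' @rdname behavior_names
#' @export
trait_names <- function() {
  c("extraversion", "agreeableness", "conscientiousness",
    "neuroticism", "openness")
}

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
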