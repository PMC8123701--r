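#' Jenks natural-breaks classification of a one-dimensional sample
#'
#' Partitions a numeric sample into `k` classes that are contiguous intervals
#' of the sorted values, minimizing the sum of squared deviations from class
#' means (SDCM). Fit quality is summarized by the goodness of variance fit,
#' GVF = 1 - SDCM/SDAM, where SDAM is the sum of squared deviations about the
#' grand mean; GVF is 0 for a single class and 1 when every class is constant.
#'
#' Two solvers are available. `"dp"` (the default) is exact dynamic
#' programming over contiguous partitions of the distinct values (O(k * m^2)
#' for m distinct values), which guarantees the global SDCM minimum and never
#' splits tied values across classes. `"greedy"` is the classical iterative
#' exchange: starting from a quantile partition, single observations are moved
#' across adjacent class boundaries while SDCM decreases; it can stall in a
#' local optimum and is provided for comparison.
#'
#' @param values Numeric vector, length >= k, no NAs.
#' @param k Number of classes (>= 1). Must not exceed the number of distinct
#'   values.
#' @param method `"dp"` (exact, default) or `"greedy"` (iterative exchange).
#' @return An object of class `jenks_breaks`: a list with `k`, `class_of`
#'   (class index 1..k per input observation, classes ordered by value),
#'   `boundaries` (data frame of per-class observed lower/upper values and
#'   sizes), `sdam`, `sdcm`, `sdbc`, and `gvf`.
#' @export
#' @examples
#' fit_breaks(c(1, 1, 1, 10, 10, 10), k = 2)
fit_breaks <- function(values, k, method = c("dp", "greedy")) {
  method <- match.arg(method)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop_input("'values' must be a finite numeric vector without NAs")
  n <- length(values)
  if (k < 1 || k != round(k)) stop_input("'k' must be a positive integer")
  if (n < k) stop_input("need at least k = %d observations, got %d", k, n)
  u <- sort(unique(values))
  m <- length(u)
  if (k > m)
    stop_input("infeasible: k = %d exceeds the %d distinct values", k, m)

  w <- as.numeric(table(factor(values, levels = u)))  # tie multiplicities
  if (method == "dp") {
    ends <- jenks_dp(u, w, k)
  } else {
    ends <- jenks_greedy(u, w, k)
  }
  # ends[g] = index into u of the last distinct value in class g
  starts <- c(1L, head(ends, -1L) + 1L)
  cls_of_unique <- rep(seq_len(k), times = ends - starts + 1L)
  class_of <- cls_of_unique[match(values, u)]

  g <- gvf_of(values, class_of)
  boundaries <- data.frame(
    class = seq_len(k),
    lower = u[starts],
    upper = u[ends],
    n = as.integer(tapply(rep(1, n), factor(class_of, levels = seq_len(k)), sum))
  )
  structure(
    list(k = k, class_of = class_of, boundaries = boundaries,
         sdam = g$sdam, sdcm = g$sdcm, sdbc = g$sdbc, gvf = g$gvf,
         method = method),
    class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(sprintf("Jenks natural breaks: k = %d classes (%s solver)\n", x$k, x$method))
  print(x$boundaries, row.names = FALSE)
  cat(sprintf("SDAM = %.6g  SDCM = %.6g  SDBC = %.6g  GVF = %.4f\n",
              x$sdam, x$sdcm, x$sdbc, x$gvf))
  invisible(x)
}

# Exact DP over contiguous partitions of distinct values u with weights w.
# Returns the vector of class end-indices (length k). Ties in cost are broken
# toward later split points, i.e. smaller lower classes.
jenks_dp <- function(u, w, k) {
  m <- length(u)
  W <- cumsum(w)
  S <- cumsum(w * u)
  Q <- cumsum(w * u^2)
  seg_cost <- function(i, j) {  # weighted SSE of u[i..j]
    ww <- W[j] - if (i > 1) W[i - 1] else 0
    ss <- S[j] - if (i > 1) S[i - 1] else 0
    qq <- Q[j] - if (i > 1) Q[i - 1] else 0
    qq - ss^2 / ww
  }
  D <- matrix(Inf, nrow = k, ncol = m)     # D[g, j]: best cost of u[1..j] in g classes
  B <- matrix(NA_integer_, nrow = k, ncol = m)
  for (j in seq_len(m)) D[1, j] <- seg_cost(1, j)
  if (k > 1) {
    for (g in 2:k) {
      for (j in g:m) {
        best <- Inf; best_i <- NA_integer_
        for (i in g:j) {  # class g covers u[i..j]
          cand <- D[g - 1, i - 1] + seg_cost(i, j)
          if (cand < best - 1e-12 ||
              (cand <= best + 1e-12 && (is.na(best_i) || i > best_i))) {
            best <- min(best, cand); best_i <- i
          }
        }
        D[g, j] <- best
        B[g, j] <- best_i
      }
    }
  }
  ends <- integer(k)
  ends[k] <- m
  if (k > 1) {
    j <- m
    for (g in k:2) {
      i <- B[g, j]
      ends[g - 1] <- i - 1L
      j <- i - 1L
    }
  }
  ends
}

# Classical exchange heuristic: start from an equal-count quantile partition of
# the distinct values, then move one boundary value between adjacent classes
# whenever the move lowers the weighted SDCM; stop at a local optimum.
jenks_greedy <- function(u, w, k) {
  m <- length(u)
  ends <- unique(round(seq_len(k) * m / k))
  ends[k] <- m
  # ensure strictly increasing ends (each class non-empty)
  for (g in seq_len(k - 1)) if (g > 1 && ends[g] <= ends[g - 1]) ends[g] <- ends[g - 1] + 1L
  sdcm_of <- function(e) {
    s <- c(1L, head(e, -1L) + 1L)
    tot <- 0
    for (g in seq_len(k)) {
      idx <- s[g]:e[g]
      mu <- sum(w[idx] * u[idx]) / sum(w[idx])
      tot <- tot + sum(w[idx] * (u[idx] - mu)^2)
    }
    tot
  }
  cur <- sdcm_of(ends)
  repeat {
    improved <- FALSE
    for (g in seq_len(k - 1)) {
      sz_g  <- ends[g] - (if (g > 1) ends[g - 1] else 0L)
      sz_g1 <- ends[g + 1] - ends[g]
      # shift boundary left (give top value of class g to class g+1)
      if (sz_g > 1) {
        e2 <- ends; e2[g] <- e2[g] - 1L
        v <- sdcm_of(e2)
        if (v < cur - 1e-12) { ends <- e2; cur <- v; improved <- TRUE; next }
      }
      # shift boundary right
      if (sz_g1 > 1) {
        e2 <- ends; e2[g] <- e2[g] + 1L
        v <- sdcm_of(e2)
        if (v < cur - 1e-12) { ends <- e2; cur <- v; improved <- TRUE }
      }
    }
    if (!improved) break
  }
  ends
}

#' Variance decomposition and goodness of variance fit for a partition
#'
#' Computes SDAM (squared deviations about the grand mean), SDCM (about class
#' means), SDBC (between classes; SDAM = SDCM + SDBC), and GVF = 1 - SDCM/SDAM
#' for a given class assignment. The assignment must define classes that are
#' contiguous intervals of the sorted values. A zero-variance sample is
#' reported as a perfect fit (GVF = 1).
#'
#' @param values Numeric vector.
#' @param assignment Integer class per observation, same length as `values`.
#' @return A list with `sdam`, `sdcm`, `sdbc`, `gvf`.
#' @export
gvf_of <- function(values, assignment) {
  if (length(values) != length(assignment))
    stop_input("'values' and 'assignment' lengths differ")
  # contiguity check: ordered by value, class labels must be non-decreasing
  # (up to relabeling classes by their mean); tied values may share a boundary.
  o <- order(values, assignment)
  lab <- assignment[o]
  if (is.unsorted(lab))
    stop_input("assignment is not a contiguous partition of the sorted values")
  sdam <- sum((values - mean(values))^2)
  cm <- tapply(values, assignment, mean)
  sdcm <- sum((values - cm[as.character(assignment)])^2)
  sdbc <- sdam - sdcm
  gvf <- if (sdam > 0) 1 - sdcm / sdam else 1
  list(sdam = sdam, sdcm = sdcm, sdbc = sdbc, gvf = gvf)
}

#' Elbow selection of the number of natural-breaks classes
#'
#' Fits optimal breaks for each k in `k_range`, then picks the smallest k
#' whose marginal GVF gain going to k+1 falls below `min_gain` — the point
#' where adding another class no longer buys meaningful explained variance.
#'
#' @param values Numeric vector to classify.
#' @param k_range Integer vector of candidate class counts (default 2:7).
#' @param min_gain Minimum worthwhile GVF improvement (default 0.01).
#' @return A list with `k_star` and `gvf_table` (data frame of k and gvf).
#' @seealso [elbow_from_gvf()] for applying the rule to a precomputed GVF table.
#' @export
select_k_elbow <- function(values, k_range = 2:7, min_gain = 0.01) {
  k_range <- sort(unique(as.integer(k_range)))
  m <- length(unique(values))
  k_range <- k_range[k_range <= m & k_range >= 1]
  if (length(k_range) == 0) stop_input("no feasible k in 'k_range'")
  gvf <- vapply(k_range, function(k) fit_breaks(values, k)$gvf, numeric(1))
  tab <- data.frame(k = k_range, gvf = gvf)
  list(k_star = elbow_from_gvf(tab, min_gain), gvf_table = tab)
}

#' Apply the elbow rule to a GVF-by-k table
#'
#' @param gvf_table Data frame with columns `k` and `gvf` (consecutive k), or
#'   a named/plain numeric GVF vector for consecutive k starting at `k_from`.
#' @param min_gain Minimum worthwhile GVF improvement (default 0.01).
#' @param k_from First k when `gvf_table` is a bare vector (default 2).
#' @return The selected k: the smallest k whose gain to k+1 is below
#'   `min_gain`; falls back to the largest k (with a warning) if gains never
#'   drop below the threshold.
#' @export
#' @examples
#' # five-class choice on a published risk-index GVF profile
#' elbow_from_gvf(c(0.617, 0.887, 0.947, 0.971, 0.976, 0.987), min_gain = 0.01)
elbow_from_gvf <- function(gvf_table, min_gain = 0.01, k_from = 2L) {
  if (is.data.frame(gvf_table)) {
    ks <- gvf_table$k; gv <- gvf_table$gvf
  } else {
    gv <- as.numeric(gvf_table); ks <- seq.int(k_from, length.out = length(gv))
  }
  if (min_gain <= 0) stop_input("'min_gain' must be positive")
  if (length(gv) == 1) return(ks[1])
  gains <- diff(gv)
  hit <- which(gains < min_gain)
  if (length(hit) == 0) {
    warning("GVF gains never fell below min_gain; returning the largest k")
    return(ks[length(ks)])
  }
  ks[hit[1]]
}
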