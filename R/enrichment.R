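#' Expected overlap of independent SNP sets
#'
#' Under independence within a universe of \code{universe_n} items, two
#' sets of sizes \eqn{n_1, n_2} share \eqn{n_1 n_2 / N} items in
#' expectation; three sets share \eqn{n_1 n_2 n_3 / N^2}.
#'
#' @param set_sizes two or three set sizes.
#' @param universe_n universe size (> 0).
#' @return expected overlap count.
#' @export
expected_overlap <- function(set_sizes, universe_n) {
  if (universe_n <= 0) stop("universe size must be positive")
  if (any(set_sizes > universe_n)) stop("set size exceeds universe size")
  k <- length(set_sizes)
  if (!k %in% 2:3) stop("only pairwise and triple overlaps are supported")
  prod(set_sizes) / universe_n^(k - 1)
}

#' Overlap enrichment test
#'
#' Pairwise overlaps use the exact hypergeometric upper tail
#' \eqn{P(X \ge observed)}; triple overlaps use a Poisson upper tail at
#' the independence mean (an approximation, flagged in the result, since
#' the exact triple-intersection null has no standard closed form).
#'
#' @param observed observed intersection size.
#' @param set_sizes two or three set sizes.
#' @param universe_n universe size.
#' @return object of class \code{overlap_result}: universe and set sizes,
#'   degree, observed, expected, fold (= observed/expected), p, and
#'   \code{method}.
#' @export
overlap_test <- function(observed, set_sizes, universe_n) {
  expected <- expected_overlap(set_sizes, universe_n)
  if (observed < 0 || observed > min(set_sizes))
    stop("observed overlap outside [0, min(set sizes)]")
  degree <- length(set_sizes)
  if (degree == 2) {
    p <- stats::phyper(observed - 1, set_sizes[1], universe_n - set_sizes[1],
                       set_sizes[2], lower.tail = FALSE)
    method <- "hypergeometric"
  } else {
    p <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
    method <- "poisson_approximation"
  }
  structure(list(universe_n = universe_n, set_sizes = set_sizes,
                 degree = degree, observed = observed, expected = expected,
                 fold = if (expected > 0) observed / expected else NA_real_,
                 p = p, method = method),
            class = "overlap_result")
}

#' @export
#' @method print overlap_result
print.overlap_result <- function(x, ...) {
  cat(sprintf("%d-way overlap in universe of %s: observed %d, expected %.2f, fold %.2f, p = %.3g (%s)\n",
              x$degree, format(x$universe_n, big.mark = ","), x$observed,
              x$expected, x$fold, x$p, x$method))
  invisible(x)
}

#' Overlap test from explicit identifier sets
#'
#' Convenience wrapper: computes the observed intersection by exact string
#' matching and calls [overlap_test()].
#'
#' @param sets list of 2 or 3 character vectors of SNP identifiers.
#' @param universe_n universe size.
#' @return an \code{overlap_result}.
#' @export
overlap_test_sets <- function(sets, universe_n) {
  sets <- lapply(sets, unique)
  observed <- length(Reduce(intersect, sets))
  overlap_test(observed, lengths(sets), universe_n)
}
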