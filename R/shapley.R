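#' Exact Shapley values by subset enumeration
#'
#' Computes, for each feature `j`, the average marginal contribution over
#' all coalitions:
#' \deqn{\phi_j = \sum_{S \subseteq F \setminus \{j\}}
#'   \frac{|S|! (p-|S|-1)!}{p!} \left(\nu(S \cup \{j\}) - \nu(S)\right)}
#' This is the brute-force oracle used to validate the fast tree path; it
#' enumerates all \eqn{2^p} subsets and is refused for `p > 12`.
#'
#' @param value_function Function taking an integer vector of feature
#'   indices (a subset of `1:p`, possibly empty) and returning a scalar.
#' @param p Number of features.
#' @return Numeric vector of length `p` of Shapley values. Satisfies the
#'   efficiency identity `sum(phi) = v(1:p) - v(integer(0))`.
#' @export
exact_shapley <- function(value_function, p) {
  stopifnot(is.function(value_function), p >= 1)
  if (p > 12) {
    stopf("exact Shapley enumeration refused for p = %d (> 12 features); use the tree-path approximation", p)
  }
  n_sub <- bitwShiftL(1L, p)
  masks <- 0:(n_sub - 1L)
  bits <- bitwShiftL(1L, 0:(p - 1L))
  v <- vapply(masks, function(m) {
    value_function(which(bitwAnd(m, bits) > 0L))
  }, numeric(1))
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bits) > 0L), numeric(1))
  w <- factorial(0:(p - 1L)) * factorial(p - 1L - (0:(p - 1L))) / factorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- bitwAnd(masks, bits[j]) == 0L
    m0 <- masks[without]
    phi[j] <- sum(w[sizes[without] + 1L] * (v[bitwOr(m0, bits[j]) + 1L] - v[m0 + 1L]))
  }
  phi
}
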