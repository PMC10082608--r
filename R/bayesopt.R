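# Sequential model-based (Bayesian) minimization of a black-box objective
# over a box, with a Gaussian-process surrogate (squared-exponential
# kernel on the unit cube) and expected-improvement acquisition over a
# fresh Latin-hypercube candidate pool each iteration. Small and
# deterministic given the seed; adequate for low-dimensional
# hyperparameter search such as (log C, log epsilon) for SVR.

gp_fit <- function(X, y, lengthscale = 0.3, nugget = 1e-6) {
  mu <- mean(y)
  s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) s <- 1
  ys <- (y - mu) / s
  d2 <- as.matrix(stats::dist(X))^2
  K <- exp(-0.5 * d2 / lengthscale^2) + diag(nugget, nrow(X))
  list(X = X, alpha = solve(K, ys), Kinv = solve(K), mu = mu, s = s,
       lengthscale = lengthscale)
}

gp_predict <- function(gp, Xnew) {
  n <- nrow(Xnew)
  m <- nrow(gp$X)
  d2 <- matrix(0, n, m)
  for (j in seq_len(ncol(Xnew))) {
    d2 <- d2 + outer(Xnew[, j], gp$X[, j], `-`)^2
  }
  kx <- exp(-0.5 * d2 / gp$lengthscale^2)
  mean_s <- drop(kx %*% gp$alpha)
  var_s <- pmax(1 - rowSums((kx %*% gp$Kinv) * kx), 1e-12)
  list(mean = gp$mu + gp$s * mean_s, sd = gp$s * sqrt(var_s))
}

# objective: function of a numeric vector in [lower, upper].
# init_points: matrix (rows = points, original scale) always evaluated
# first; the first row is the "anchor" whose objective value is reported.
bayes_opt_min <- function(objective, lower, upper, n_evals,
                          init_points = NULL, seed = 1L,
                          n_candidates = 256L) {
  d <- length(lower)
  stopifnot(length(upper) == d, n_evals >= 1)
  span <- upper - lower
  fixed <- span <= 0
  if (all(fixed)) {
    y <- objective(lower)
    return(list(par = lower, value = y, anchor_value = y,
                X = matrix(lower, 1), y = y))
  }
  to_unit <- function(x) ifelse(fixed, 0.5, (x - lower) / ifelse(fixed, 1, span))
  from_unit <- function(u) lower + u * ifelse(fixed, 0, span)

  with_rng(seed, {
    init_u <- NULL
    if (!is.null(init_points)) {
      init_u <- t(apply(init_points, 1, to_unit))
    }
    n0 <- min(max(d + 3L, 5L), n_evals)
    n_lhs <- max(n0 - NROW(init_u), 0L)
    U <- rbind(init_u,
               if (n_lhs > 0) lhs::randomLHS(n_lhs, d))
    U <- U[seq_len(min(nrow(U), n_evals)), , drop = FALSE]
    y <- apply(U, 1, function(u) objective(from_unit(u)))
    anchor_value <- y[1]

    while (length(y) < n_evals) {
      cand <- lhs::randomLHS(n_candidates, d)
      gp <- tryCatch(gp_fit(U, y), error = function(e) NULL)
      if (is.null(gp)) {
        pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      } else {
        pr <- gp_predict(gp, cand)
        imp <- min(y) - pr$mean
        z <- imp / pr$sd
        ei <- imp * stats::pnorm(z) + pr$sd * stats::dnorm(z)
        pick <- cand[which.max(ei), , drop = FALSE]
      }
      U <- rbind(U, pick)
      y <- c(y, objective(from_unit(drop(pick))))
    }
    best <- which.min(y)
    list(par = from_unit(U[best, ]), value = y[best],
         anchor_value = anchor_value,
         X = t(apply(U, 1, from_unit)), y = y)
  })
}
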