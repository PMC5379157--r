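# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (no IRLS, no step-up trick, no weighted-mean
# helpers) so that agreement is evidence, not tautology.

# Two-parameter logistic likelihood on a collapsed 2x3 genotype table,
# maximized by Newton's method on (intercept, trend) from a coarse grid start.
oracle_logistic_2x3 <- function(controls, cases) {
  g <- c(0, 1, 2)
  nll <- function(th) {
    eta <- th[1] + th[2] * g
    -sum(cases * eta - (cases + controls) * log1p(exp(eta)))
  }
  grad <- function(th) {
    eta <- th[1] + th[2] * g
    mu <- plogis(eta)
    r <- cases - (cases + controls) * mu
    -c(sum(r), sum(r * g))
  }
  hess <- function(th) {
    eta <- th[1] + th[2] * g
    w <- (cases + controls) * plogis(eta) * (1 - plogis(eta))
    m <- rbind(c(sum(w), sum(w * g)), c(sum(w * g), sum(w * g^2)))
    m
  }
  starts <- expand.grid(a = seq(-2, 2, by = 0.5), b = seq(-2, 2, by = 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th <- as.numeric(starts[i, ])
    th <- tryCatch({
      for (it in 1:100) {
        step <- solve(hess(th), grad(th))
        th <- th - step
        if (max(abs(step)) < 1e-12) break
      }
      th
    }, error = function(e) NULL)   # divergent start: saturated Hessian
    if (is.null(th) || !all(is.finite(th))) next
    if (is.null(best) || nll(th) < nll(best)) best <- th
  }
  list(beta = best[2], se = sqrt(solve(hess(best))[2, 2]))
}

# Exact permutation p-value for the continuity-corrected Begg statistic at
# small n: permutes the deviate vector against the fixed variance ranking.
oracle_begg_permutation_p <- function(t, v) {
  n <- length(t)
  kendall_s <- function(x, y) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign((x[i] - x[j]) * (y[i] - y[j]))
    s
  }
  s_obs <- abs(kendall_s(t, v))
  perms <- gtools_permutations(n)
  s_all <- apply(perms, 1, function(idx) abs(kendall_s(t[idx], v)))
  mean(s_all >= s_obs)
}

# All permutations of 1..n (tiny n only), no external dependency.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in 1:n) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# One-degree-of-freedom Hardy-Weinberg chi-square p-value from genotype counts.
oracle_hwe_p <- function(g) {
  n <- length(g)
  p <- mean(g) / 2
  exp_counts <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- tabulate(g + 1L, nbins = 3L)
  x2 <- sum((obs - exp_counts)^2 / pmax(exp_counts, 1e-12))
  pchisq(x2, df = 1, lower.tail = FALSE)
}
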