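# Brute-force oracles kept independent of the implementation paths they
# check.

# exhaustive best-path search for the copy-number HMM
brute_force_viterbi <- function(obs, means, sigmas, weights, tau = 1e-4) {
  k <- length(means)
  n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  lp <- apply(paths, 1, function(p) {
    v <- log(weights[p[1]]) + sum(dnorm(obs, means[p], sigmas[p], log = TRUE))
    if (n > 1) {
      v <- v + sum(ifelse(diff(p) == 0, log(1 - tau), log(tau / (k - 1))))
    }
    v
  })
  as.integer(paths[which.max(lp), ])
}

# exact two-sided Wilcoxon p by enumerating all group assignments of ranks
brute_force_wilcoxon_p <- function(a, b) {
  na <- length(a)
  n <- na + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  ew <- na * (n + 1) / 2
  sets <- utils::combn(n, na)
  ws <- colSums(matrix(r[sets], nrow = na))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}

# hypergeometric enumeration for the two-sided Fisher p
brute_force_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct product-limit computation over risk sets
brute_force_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  surv <- numeric(length(ts))
  s <- 1
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(event & time == ts[i])
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ts, survival = surv)
}
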