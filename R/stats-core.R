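# Native statistical primitives used throughout the pipeline. Each test
# returns a one-row tibble so results bind rowwise into tidy summary tables.

test_result <- function(statistic, p_value, df = NA_real_, method) {
  tibble::tibble(
    method = method,
    statistic = as.numeric(statistic),
    df = as.numeric(df),
    p_value = as.numeric(p_value)
  )
}

#' Two-sided Fisher's exact test for a 2x2 contingency table
#'
#' Computes the exact two-sided p-value by the point-probability rule: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#' A relative tolerance guards against floating-point exclusion of tied
#' tables.
#'
#' @param a,b,c,d Non-negative integer counts; rows are groups, columns are
#'   mutated/unmutated (or any two outcomes).
#' @param tie_tol Relative tolerance when comparing point probabilities.
#' @return A one-row tibble with columns `method`, `statistic` (sample odds
#'   ratio), `df` and `p_value`.
#' @examples
#' fisher_exact_2x2(4, 13, 5, 287) # p ~ 7e-4
#' @export
fisher_exact_2x2 <- function(a, b, c, d, tie_tol = 1e-7) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) {
    stop("degenerate all-zero table")
  }
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  p_obs <- logp[x == a]
  p_two <- sum(exp(logp[logp <= p_obs + log1p(tie_tol)]))
  or <- (a * d) / (b * c)
  test_result(or, min(1, p_two), method = "fisher")
}

#' Welch's unequal-variance t test
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble with the t statistic, Welch-Satterthwaite
#'   degrees of freedom and the two-sided p-value.
#' @export
welch_t <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a)
  nb <- length(values_b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 observations")
  ma <- mean(values_a)
  mb <- mean(values_b)
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    # both variances zero: identical means give p = 1, separated means p = 0
    if (ma == mb) return(test_result(0, 1, df = na + nb - 2, method = "welch_t"))
    return(test_result(sign(ma - mb) * Inf, 0, df = na + nb - 2, method = "welch_t"))
  }
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * stats::pt(-abs(tstat), df)
  test_result(tstat, p, df = df, method = "welch_t")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in the input order: `q_i = min_{j >= rank(i)} m p_(j)/j`
#' clipped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

#' Wilcoxon rank-sum test with midrank ties
#'
#' Uses exact enumeration of all group assignments when the combined sample
#' size is at most `exact_limit`, otherwise a normal approximation with
#' tie-corrected variance and continuity correction. The exact two-sided
#' p-value is the probability of a rank-sum at least as far from its null
#' expectation as the observed one.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param exact_limit Combined sample size at or below which the exact
#'   enumeration path is used.
#' @return A one-row tibble; `statistic` is the rank sum of `values_a`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b, exact_limit = 12) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  na <- length(values_a)
  nb <- length(values_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  n <- na + nb
  r <- rank(c(values_a, values_b))
  w <- sum(r[seq_len(na)])
  ew <- na * (n + 1) / 2
  if (n <= exact_limit) {
    sets <- utils::combn(n, na)
    ws <- colSums(matrix(r[sets], nrow = na))
    p <- mean(abs(ws - ew) >= abs(w - ew) - 1e-9)
    return(test_result(w, p, method = "wilcoxon"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  varw <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (varw <= 0) return(test_result(w, 1, method = "wilcoxon"))
  dev <- w - ew
  z <- (dev - sign(dev) * 0.5) / sqrt(varw)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(w, p, method = "wilcoxon")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records Data frame with columns `time` (non-negative) and `event`
#'   (logical or 0/1; TRUE means death/failure observed).
#' @return A tibble with one row per distinct event/censoring time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`. Survival is 1 at
#'   time 0 and drops only at event times.
#' @export
km_estimate <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (nrow(records) == 0) stop("at least one record required")
  if (any(records$time < 0)) stop("negative survival time")
  dat <- dplyr::arrange(tibble::as_tibble(records), .data$time)
  dat$event <- as.logical(dat$event)
  out <- dat |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(
      n_event = sum(.data$event),
      n_censor = sum(!.data$event),
      .groups = "drop"
    )
  n <- nrow(dat)
  at_risk <- n - cumsum(dplyr::lag(out$n_event + out$n_censor, default = 0))
  surv <- cumprod(1 - out$n_event / at_risk)
  tibble::tibble(
    time = out$time,
    n_risk = at_risk,
    n_event = out$n_event,
    n_censor = out$n_censor,
    survival = surv
  )
}

#' Survival probability from a Kaplan-Meier table at given times
#'
#' @param km Output of [km_estimate()].
#' @param times Numeric vector of times.
#' @return Survival probabilities (1 before the first drop).
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(t) {
    idx <- which(km$time <= t)
    if (length(idx) == 0) 1 else km$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Unweighted log-rank test: observed minus expected events in group 1,
#' summed over shared event times, with the hypergeometric variance;
#' chi-square statistic on 1 degree of freedom.
#'
#' @param records Data frame with columns `time`, `event`, `group` (exactly
#'   two distinct group labels).
#' @return A one-row tibble with the chi-square statistic and p-value.
#' @export
logrank_test <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  dat <- tibble::as_tibble(records)
  dat$event <- as.logical(dat$event)
  groups <- sort(unique(as.character(dat$group)))
  if (length(groups) != 2) stop("exactly two groups required")
  if (any(table(dat$group) == 0)) stop("empty group")
  if (!any(dat$event)) stop("at least one event required")
  g1 <- as.character(dat$group) == groups[1]
  event_times <- sort(unique(dat$time[dat$event]))
  o_minus_e <- 0
  v <- 0
  for (t in event_times) {
    at_risk <- dat$time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(dat$event & dat$time == t)
    d1_j <- sum(dat$event & dat$time == t & g1)
    o_minus_e <- o_minus_e + d1_j - d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n_j - d_j) * n1_j * (n_j - n1_j) / (n_j^2 * (n_j - 1))
    }
  }
  if (v <= 0) return(test_result(0, 1, df = 1, method = "logrank"))
  chisq <- o_minus_e^2 / v
  test_result(chisq, stats::pchisq(chisq, df = 1, lower.tail = FALSE),
              df = 1, method = "logrank")
}
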