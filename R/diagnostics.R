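# Convergence diagnostics: split-chain R-hat and an initial-positive-
# sequence effective sample size. Both operate on plain numeric vectors so
# they can be reused on any scalar chain.

split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    n <- length(ch)
    if (n < 4L) return(NA_real_)
    h <- n %/% 2L
    halves <- c(halves, list(ch[seq_len(h)], ch[(n - h + 1L):n]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1L))
  vars <- vapply(halves, stats::var, numeric(1L))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(if (B == 0 || !is.finite(B)) 1 else NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_chain <- function(x, max_lag = NULL) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 1000L)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[-1L]
  # Geyer initial positive sequence: sum consecutive-lag pairs while positive
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, min(n, n / (1 + 2 * s)))
}

# Monte-Carlo standard error of a chain mean, using the ESS
mc_se <- function(x) stats::sd(x) / sqrt(ess_chain(x))
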