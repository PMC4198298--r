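# Independent oracle implementations used to validate package code.
# These are deliberately naive and share no code with R/.

# Benjamini-Hochberg step-up, literal definition:
# on the sorted vector q(i) = min_{j >= i} min(1, m p(j) / j), mapped back.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(1, m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Newton-Raphson maximum partial-likelihood fit for a single covariate,
# Breslow risk sets (data simulated continuously -> no ties, so this matches
# Efron). Plain R, no package code.
cox_nr_oracle <- function(x, time, event, tol = 1e-10, max_iter = 50) {
  ord <- order(time)
  x <- x[ord]; event <- event[ord]
  n <- length(x)
  beta <- 0
  for (it in seq_len(max_iter)) {
    eta <- exp(beta * x)
    s0 <- rev(cumsum(rev(eta)))
    s1 <- rev(cumsum(rev(eta * x)))
    s2 <- rev(cumsum(rev(eta * x^2)))
    U <- sum(event * (x - s1 / s0))
    I <- sum(event * (s2 / s0 - (s1 / s0)^2))
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  eta <- exp(beta * x)
  s0 <- rev(cumsum(rev(eta)))
  s1 <- rev(cumsum(rev(eta * x)))
  s2 <- rev(cumsum(rev(eta * x^2)))
  I <- sum(event * (s2 / s0 - (s1 / s0)^2))
  list(beta = beta, se = 1 / sqrt(I), z = beta * sqrt(I))
}

# brute-force risk score: explicit double loop over samples and model genes
risk_score_brute <- function(model, expr) {
  sapply(colnames(expr), function(s) {
    total <- 0
    for (i in seq_len(nrow(model))) {
      g <- model$gene[i]
      total <- total + model$z[i] * (expr[g, s] - model$mu[i]) / model$tau[i]
    }
    total
  })
}

# Kaplan-Meier with no censoring equals one minus the empirical CDF
km_ecdf_oracle <- function(time) {
  t_sorted <- sort(unique(time))
  data.frame(time = t_sorted,
             survival = sapply(t_sorted, function(t) mean(time > t)))
}

# tiny survival cohort wrapper around raw pieces
make_cohort <- function(expr, time, event, name = "test") {
  survival_cohort(expr,
                  tibble::tibble(sample_id = colnames(expr),
                                 time = time, event = event),
                  name = name)
}
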