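# Independent oracles, deliberately written as naive textbook
# implementations on a different code path from the package: explicit
# risk-set loops for the partial likelihood, a first-order proximal
# (FISTA) minimizer for the penalized objective, the product-limit formula
# for Kaplan-Meier, and the hypergeometric log-rank sums.

# Breslow log partial likelihood via explicit risk-set loops
naive_logpl <- function(beta, x, time, event) {
  eta <- drop(x %*% beta)
  ll <- 0
  for (i in which(event == 1)) {
    R <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[R])))
  }
  unname(ll)
}

naive_grad <- function(beta, x, time, event) {
  eta <- drop(x %*% beta)
  g <- numeric(length(beta))
  for (i in which(event == 1)) {
    R <- which(time >= time[i])
    w <- exp(eta[R]); w <- w / sum(w)
    g <- g + x[i, ] - drop(w %*% x[R, , drop = FALSE])
  }
  unname(g)
}

# proximal-gradient (FISTA with backtracking) minimizer of
# F(b) = -logPL(b) + lambda*alpha*||b||_1 + lambda*(1-alpha) b'Qb
fista_oracle <- function(x, time, event, Q, lambda, alpha,
                         max_iter = 100000, tol = 1e-12) {
  p <- ncol(x)
  f <- function(b) -naive_logpl(b, x, time, event) +
    lambda * (1 - alpha) * drop(crossprod(b, Q %*% b))
  gf <- function(b) -naive_grad(b, x, time, event) +
    2 * lambda * (1 - alpha) * drop(Q %*% b)
  F_obj <- function(b) f(b) + lambda * alpha * sum(abs(b))
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  b <- numeric(p); y <- b; tk <- 1; L <- 1
  Fb <- F_obj(b)
  for (k in seq_len(max_iter)) {
    g <- gf(y); fy <- f(y)
    repeat {
      bn <- soft(y - g / L, lambda * alpha / L)
      d <- bn - y
      if (f(bn) <= fy + sum(g * d) + (L / 2) * sum(d^2) + 1e-14) break
      L <- L * 2
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- bn + ((tk - 1) / tk1) * (bn - b)
    Fn <- F_obj(bn)
    if (abs(Fb - Fn) < tol * (1 + abs(Fn)) && max(abs(bn - b)) < 1e-10) {
      b <- bn; Fb <- Fn
      break
    }
    b <- bn; Fb <- Fn; tk <- tk1
    L <- L / 1.5
  }
  list(beta = b, objective = Fb, iters = k)
}

# textbook product-limit estimator at distinct event times
textbook_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out$survival[k] <- s
  }
  out
}

# textbook two-group log-rank chi-square (hypergeometric moments)
textbook_logrank_chi2 <- function(time, event, in_a) {
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n1 <- sum(at_risk & in_a); n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_a)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# univariate MMLE by grid-refined numeric maximization of the naive logpl
numeric_mmle <- function(xk, time, event, bound = 16) {
  opt <- optimize(function(b) -naive_logpl(b, matrix(xk), time, event),
                  c(-bound, bound), tol = 1e-10)
  opt$minimum
}
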