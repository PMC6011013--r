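# Breslow-form Cox partial likelihood and derivatives.
#
# All quantities are computed on data sorted by increasing observed time,
# with tied event times sharing one risk-set denominator (Breslow). For
# sorted times, the risk set of an event at time t is every patient with
# observed time >= t, so denominators are reverse cumulative sums of
# exp(eta) anchored at the first index of each tie group.

cox_order <- function(time, event) {
  ord <- order(time)
  t_s <- time[ord]
  # first/last index of the tie group containing each sorted position
  r <- rle(t_s)
  ends <- cumsum(r$lengths)
  first <- rep.int(ends - r$lengths + 1L, r$lengths)
  last <- rep.int(ends, r$lengths)
  list(ord = ord, time = t_s, event = as.numeric(event[ord]),
       first = first, last = last)
}

# log partial likelihood, per-sample eta-gradient and diagonal eta-curvature
# at linear predictor eta (in original patient order)
cox_eta_derivs <- function(eta, oo) {
  e <- eta[oo$ord] - mean(eta)
  ex <- exp(e)
  revcs <- rev(cumsum(rev(ex)))          # sum_{j >= i} exp(eta_j)
  D <- revcs[oo$first]                   # risk-set denominator per position
  d <- oo$event
  logpl <- sum(d * (e - log(D)))
  # cumulative event mass: A_i = sum over events with t_k <= t_i of 1/D_k
  A <- cumsum(d / D)[oo$last]
  B <- cumsum(d / D^2)[oo$last]
  g_s <- d - ex * A
  w_s <- ex * A - ex^2 * B
  g <- numeric(length(eta)); w <- numeric(length(eta))
  g[oo$ord] <- g_s
  w[oo$ord] <- pmax(w_s, 0)
  list(logpl = logpl, grad_eta = g, w = w)
}

#' Cox log partial likelihood
#'
#' Evaluates `l(beta) = sum_{i: event} [x_i' beta - log sum_{j in R(t_i)}
#' exp(x_j' beta)]` where `R(t)` is the risk set just before time `t`;
#' tied event times share one risk-set log-sum (Breslow).
#'
#' @param beta Coefficient vector, one entry per matrix column.
#' @param x Patient x gene matrix (see [as_omics_matrix()]); rows must match
#'   `surv$patient_id` in order.
#' @param surv A `survival_data` tibble.
#' @return The log partial likelihood (scalar).
#' @examples
#' surv <- survival_data(data.frame(patient_id = letters[1:3],
#'                                  time = 1:3, event = 1))
#' x <- matrix(c(1, 0, 1), 3, dimnames = list(letters[1:3], "g1"))
#' cox_logpl(0, x, surv)  # -log(6): risk sets of size 3, 2, 1
#' @export
cox_logpl <- function(beta, x, surv) {
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  if (sum(surv$event) < 1) abort("no events", class = "screennet_validation_error")
  eta <- drop(x %*% beta)
  if (any(!is.finite(eta))) abort("non-finite linear predictor")
  oo <- cox_order(surv$time, surv$event)
  cox_eta_derivs(eta, oo)$logpl
}

# gradient of logpl with respect to beta
cox_grad <- function(beta, x, oo) {
  eta <- drop(x %*% beta)
  dv <- cox_eta_derivs(eta, oo)
  drop(crossprod(x, dv$grad_eta))
}

# full d x d negative-Hessian of the log partial likelihood at beta,
# looping over distinct event times in decreasing order
cox_neg_hessian <- function(beta, x, oo) {
  xs <- x[oo$ord, , drop = FALSE]
  eta <- drop(xs %*% beta); eta <- eta - mean(eta)
  ex <- exp(eta)
  n <- nrow(xs); p <- ncol(xs)
  H <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- n
  while (i >= 1) {
    j <- oo$first[i]
    idx <- j:i                            # one tie group
    exi <- ex[idx]
    xi <- xs[idx, , drop = FALSE]
    S0 <- S0 + sum(exi)
    S1 <- S1 + drop(crossprod(xi, exi))
    S2 <- S2 + crossprod(xi * sqrt(exi))
    n_ev <- sum(oo$event[idx])
    if (n_ev > 0) {
      H <- H + n_ev * (S2 / S0 - tcrossprod(S1 / S0))
    }
    i <- j - 1L
  }
  (H + t(H)) / 2
}

check_paired <- function(x, surv) {
  if (nrow(x) != nrow(surv) || !identical(rownames(x), surv$patient_id)) {
    abort("matrix rows and survival patient ids do not match; use align_patients()",
          class = "screennet_validation_error")
  }
  invisible(TRUE)
}
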