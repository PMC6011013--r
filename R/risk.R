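#' Construct a risk model from explicit coefficients
#'
#' Builds a deployable signature directly from per-gene coefficients and
#' training standardization constants, e.g. for a marginal-coefficient
#' signature or a fixed-cutoff calibration study.
#'
#' @param genes Signature gene symbols.
#' @param beta Coefficients on the standardized scale.
#' @param train_means,train_sds Standardization constants from training
#'   data.
#' @param pi_star Optional fixed PI cutoff (bypasses the adaptive scan).
#' @param gamma_star Optional quantile level associated with `pi_star`.
#' @param method Provenance label.
#' @return A `risk_model`.
#' @export
risk_model <- function(genes, beta, train_means, train_sds,
                       pi_star = NA_real_, gamma_star = NA_real_,
                       method = "manual") {
  stopifnot(length(genes) == length(beta),
            length(genes) == length(train_means),
            length(genes) == length(train_sds))
  structure(list(genes = as.character(genes), beta = as.double(beta),
                 train_means = as.double(train_means),
                 train_sds = as.double(train_sds),
                 gamma_star = gamma_star, pi_star = pi_star,
                 lambda = NA_real_, alpha = NA_real_, method = method),
            class = "risk_model")
}

#' Build a deployable risk model from a penalized fit
#'
#' Keeps the signature (genes with nonzero coefficients) along with the
#' training standardization constants; the gamma/PI cutoff is attached by
#' [optimal_cutoff()] via [run_pipeline()] or manually.
#'
#' @param fit A `coxnet_fit`.
#' @return A `risk_model` with `genes`, `beta`, `train_means`, `train_sds`
#'   and provenance (`lambda`, `alpha`, `method`); `gamma_star` and
#'   `pi_star` are `NA` until a cutoff is chosen.
#' @export
as_risk_model <- function(fit) {
  stopifnot(inherits(fit, "coxnet_fit"))
  nz <- which(fit$beta != 0)
  structure(list(genes = fit$genes[nz], beta = unname(fit$beta[nz]),
                 train_means = unname(fit$center[nz]),
                 train_sds = unname(fit$scale[nz]),
                 gamma_star = NA_real_, pi_star = NA_real_,
                 lambda = fit$lambda, alpha = fit$alpha,
                 method = fit$method),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model:%s> %d-gene signature; gamma*=%.3g, PI*=%.4g\n",
              x$method, length(x$genes), x$gamma_star, x$pi_star))
  invisible(x)
}

#' Prognostic index
#'
#' The linear risk score `PI_i = sum_g beta_g (x_ig - mean_g) / sd_g`
#' using the model's training standardization constants, so train and test
#' patients are scored on one scale with no information leak.
#'
#' @param x Patient x gene matrix containing all signature genes.
#' @param model A `risk_model`.
#' @return Named numeric vector of per-patient scores.
#' @export
prognostic_index <- function(x, model) {
  x <- as_omics_matrix(x)
  missing_genes <- setdiff(model$genes, colnames(x))
  if (length(missing_genes) > 0) {
    abort(paste0("signature gene(s) absent from matrix: ",
                 paste(missing_genes, collapse = ", ")),
          class = "screennet_validation_error")
  }
  if (length(model$genes) == 0) {
    return(setNames(numeric(nrow(x)), rownames(x)))
  }
  xs <- sweep(sweep(x[, model$genes, drop = FALSE], 2, model$train_means),
              2, model$train_sds, "/")
  setNames(drop(xs %*% model$beta), rownames(x))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate at each distinct event time, via
#' `survival::survfit`.
#'
#' @param surv A `survival_data` tibble.
#' @return A `km_curve` tibble with `time`, `survival`, `at_risk`,
#'   `n_events` (rows at distinct event times only).
#' @export
kaplan_meier <- function(surv) {
  stopifnot(nrow(surv) >= 1)
  sf <- survival::survfit(
    survival::Surv(surv$time, surv$event) ~ 1, conf.type = "none")
  keep <- sf$n.event > 0
  out <- tibble::tibble(time = sf$time[keep],
                        survival = sf$surv[keep],
                        at_risk = sf$n.risk[keep],
                        n_events = sf$n.event[keep])
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank via `survival::survdiff`: hypergeometric
#' expectation and variance of one group's events at each distinct event
#' time, `chi2 = (sum(O - E))^2 / sum(V)` on 1 df.
#'
#' @param surv A `survival_data` tibble.
#' @param groups Two-level vector (logical, factor or character) aligned
#'   with `surv`; `TRUE`/second level conventionally the high-risk group.
#' @return A `logrank_result` list: `chi2`, `p`, `observed`, `expected`,
#'   `n` per group.
#' @export
logrank_test <- function(surv, groups) {
  stopifnot(length(groups) == nrow(surv))
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) != 2) {
    abort("log-rank test needs exactly two non-empty groups",
          class = "screennet_validation_error")
  }
  sd_ <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ g)
  structure(list(chi2 = unname(sd_$chisq),
                 p = pchisq(unname(sd_$chisq), df = 1, lower.tail = FALSE),
                 observed = unname(sd_$obs), expected = unname(sd_$exp),
                 n = as.vector(table(droplevels(g)))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi2 = %.4f (1 df), p = %.4g; n = %s\n",
              x$chi2, x$p, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Quantile grid for the adaptive cutoff scan
#'
#' @return The 13 levels 0.20, 0.25, ..., 0.80.
#' @export
gamma_grid <- function() seq(0.20, 0.80, by = 0.05)

#' Adaptive prognostic-index cutoff on training data
#'
#' Scans gamma over 0.20, 0.25, ..., 0.80; for each level the
#' gamma-quantile `q_gamma` of the training PI (type-7, linear
#' interpolation) splits patients into high risk (`PI > q_gamma`, strictly
#' above) and low risk, and the two-group log-rank p-value is recorded.
#' Returns the gamma minimizing p (ties broken toward the smaller gamma,
#' i.e. the larger high-risk group). Levels where a group is empty are
#' skipped.
#'
#' @param pi_train Training prognostic indices.
#' @param surv_train Aligned training `survival_data`.
#' @return List with `gamma_star`, `pi_star` (= `q_{gamma*}`), `p_star`
#'   and the full `scan` tibble (`gamma`, `cutoff`, `n_high`, `chi2`, `p`).
#' @export
optimal_cutoff <- function(pi_train, surv_train) {
  stopifnot(length(pi_train) == nrow(surv_train))
  gg <- gamma_grid()
  scan <- purrr::map_dfr(gg, function(g) {
    q <- unname(quantile(pi_train, g, type = 7))
    high <- pi_train > q
    if (sum(high) == 0 || sum(!high) == 0) {
      return(tibble::tibble(gamma = g, cutoff = q, n_high = sum(high),
                            chi2 = NA_real_, p = NA_real_))
    }
    lr <- logrank_test(surv_train, high)
    tibble::tibble(gamma = g, cutoff = q, n_high = sum(high),
                   chi2 = lr$chi2, p = lr$p)
  })
  ok <- which(!is.na(scan$p))
  if (length(ok) == 0) {
    abort("every gamma level yields a degenerate split (constant PI?)",
          class = "screennet_validation_error")
  }
  best <- ok[which.min(scan$p[ok])]       # which.min takes the first tie
  list(gamma_star = scan$gamma[best], pi_star = scan$cutoff[best],
       p_star = scan$p[best], scan = scan)
}

#' Attach an adaptive cutoff to a risk model
#'
#' @param model A `risk_model`.
#' @param x_train,surv_train Training data used to scan the cutoff.
#' @return The model with `gamma_star`/`pi_star` set and the scan stored
#'   in `cutoff_scan`.
#' @export
calibrate_cutoff <- function(model, x_train, surv_train) {
  pi_tr <- prognostic_index(x_train, model)
  oc <- optimal_cutoff(pi_tr, surv_train)
  model$gamma_star <- oc$gamma_star
  model$pi_star <- oc$pi_star
  model$train_p <- oc$p_star
  model$cutoff_scan <- oc$scan
  model
}

#' Validate a risk model on held-out patients
#'
#' Scores the test patients with the training standardization, assigns
#' high risk iff `PI > pi_star` (the training cutoff; strictly above), and
#' runs the two-group log-rank test. The model never sees the test
#' survival outcomes before this call.
#'
#' @param x_test,surv_test Held-out matrix and aligned survival table.
#' @param model A calibrated `risk_model` (finite `pi_star`).
#' @return List with `logrank` (`NULL` when non-evaluable), `groups`
#'   tibble (`patient_id`, `pi`, `group`) and `evaluable` flag.
#' @export
evaluate_testset <- function(x_test, surv_test, model) {
  if (!is.finite(model$pi_star)) {
    abort("model has no calibrated cutoff; run calibrate_cutoff() first")
  }
  pi_d <- prognostic_index(x_test, model)
  high <- pi_d > model$pi_star
  groups <- tibble::tibble(patient_id = surv_test$patient_id, pi = unname(pi_d),
                           group = ifelse(high, "high", "low"))
  if (sum(high) == 0 || sum(!high) == 0) {
    return(list(logrank = NULL, groups = groups, evaluable = FALSE))
  }
  list(logrank = logrank_test(surv_test, high), groups = groups,
       evaluable = TRUE)
}
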