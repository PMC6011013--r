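# broom-style accessors for the fitted objects

#' Tidy a penalized Cox fit
#'
#' @param x A `coxnet_fit`.
#' @param nonzero_only Keep only the signature (default FALSE).
#' @param ... Unused.
#' @return Tibble with `gene` and `beta` (standardized scale).
#' @export
tidy.coxnet_fit <- function(x, nonzero_only = FALSE, ...) {
  out <- tibble::tibble(gene = x$genes, beta = unname(x$beta))
  if (nonzero_only) out <- out[out$beta != 0, , drop = FALSE]
  out
}

#' @rdname tidy.coxnet_fit
#' @export
glance.coxnet_fit <- function(x, ...) {
  tibble::tibble(method = x$method, lambda = x$lambda, alpha = x$alpha,
                 objective = x$objective, n_nonzero = sum(x$beta != 0),
                 n_iter = x$n_iter, converged = x$converged)
}

#' Tidy a screening result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return Tibble with `gene`, `marginal_beta`, `source`.
#' @export
tidy.screen_result <- function(x, ...) {
  tibble::tibble(gene = x$gene, marginal_beta = x$marginal_beta,
                 source = x$source)
}

#' @rdname tidy.screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(kind = attr(x, "kind"), d = nrow(x),
                 threshold_used = attr(x, "threshold_used"))
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_lambda`.
#' @param ... Unused.
#' @return Long tibble with `repeat_id`, `lambda`, `cvpl`.
#' @export
tidy.cv_lambda <- function(x, ...) {
  tidyr::expand_grid(repeat_id = seq_len(nrow(x$cvpl_by_lambda)),
                     lambda = x$lambda_grid) |>
    dplyr::mutate(cvpl = as.vector(t(x$cvpl_by_lambda)))
}

#' @rdname tidy.cv_lambda
#' @export
glance.cv_lambda <- function(x, ...) {
  tibble::tibble(method = x$method, k = x$settings$k,
                 repeats = x$settings$repeats, alpha = x$alpha,
                 lambda_hat = x$lambda_hat, lambda_mean = x$lambda_mean)
}

#' Tidy a risk model
#'
#' @param x A `risk_model`.
#' @param ... Unused.
#' @return Tibble with `gene`, `beta`, `train_mean`, `train_sd`.
#' @export
tidy.risk_model <- function(x, ...) {
  tibble::tibble(gene = x$genes, beta = x$beta,
                 train_mean = x$train_means, train_sd = x$train_sds)
}

#' @rdname tidy.risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(method = x$method, lambda = x$lambda, alpha = x$alpha,
                 n_signature = length(x$genes), gamma_star = x$gamma_star,
                 pi_star = x$pi_star)
}

#' Tidy a log-rank result
#'
#' @param x A `logrank_result`.
#' @param ... Unused.
#' @return One-row tibble with `chi2`, `p`.
#' @export
tidy.logrank_result <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, p = x$p)
}

#' Tidy a pipeline run
#'
#' @param x An `snp_run`.
#' @param ... Unused.
#' @return The per-threshold results tibble.
#' @export
tidy.snp_run <- function(x, ...) x$results

#' @rdname tidy.snp_run
#' @export
glance.snp_run <- function(x, ...) {
  tibble::tibble(mode = x$mode, method = x$method, alpha = x$alpha,
                 n_thresholds = nrow(x$results),
                 best_test_p = suppressWarnings(min(x$results$test_p,
                                                   na.rm = TRUE)))
}
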