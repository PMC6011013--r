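#' Adaptive signed-Laplacian network penalty
#'
#' The sparsity-plus-smoothness penalty
#' `lambda * [alpha * ||beta||_1 + (1 - alpha) * Phi(beta)]` with
#' `Phi(beta) = sum_(i,j) w_ij (sgn(bt_i) beta_i / sqrt(d_i) -
#' sgn(bt_j) beta_j / sqrt(d_j))^2`, where `bt` is a preliminary
#' coefficient estimate. Flipping coefficients by preliminary signs lets
#' adjacent genes with opposite regulation (e.g. a transcription factor
#' activating one target and repressing another) share a smooth penalty;
#' scaling by the degree lets hub genes carry larger coefficients.
#'
#' @param beta Coefficient vector in the gene order of `genes`.
#' @param weights An `adaptive_weights` object (see
#'   [make_adaptive_weights()]), or a bare sign vector.
#' @param net A `gene_network`.
#' @param genes Ordered gene symbols (defines `beta`'s order).
#' @param lambda Sparsity parameter, > 0.
#' @param alpha Network-balance parameter in (0, 1]; `alpha = 1` is the
#'   pure lasso penalty.
#' @return Penalty value (scalar).
#' @export
adalnet_penalty <- function(beta, weights, net, genes, lambda, alpha) {
  check_lambda_alpha(lambda, alpha)
  s <- weight_signs(weights, length(beta))
  d <- network_degrees(net, genes)
  e <- subnetwork(net, genes)
  smooth <- 0
  if (nrow(e) > 0) {
    i <- match(e$from, genes)
    j <- match(e$to, genes)
    smooth <- sum(e$weight *
                    (s[i] * beta[i] / sqrt(d[i]) -
                     s[j] * beta[j] / sqrt(d[j]))^2)
  }
  lambda * (alpha * sum(abs(beta)) + (1 - alpha) * smooth)
}

#' Quadratic Laplacian network penalty
#'
#' `lambda * [alpha * ||beta||_1 + (1 - alpha) * beta' L beta]` with `L`
#' the (normalized) Laplacian; the smoothness term used by the ADMM solver.
#'
#' @param beta Coefficient vector.
#' @param L Symmetric positive semi-definite Laplacian matrix.
#' @param lambda,alpha As in [adalnet_penalty()].
#' @return Penalty value (scalar).
#' @export
quad_laplacian_penalty <- function(beta, L, lambda, alpha) {
  check_lambda_alpha(lambda, alpha)
  lambda * (alpha * sum(abs(beta)) +
              (1 - alpha) * drop(crossprod(beta, L %*% beta)))
}

# Both penalties share the form lambda*alpha*||beta||_1 +
# lambda*(1-alpha)*beta' Q beta: Q = L for the plain quadratic penalty and
# Q = S L S (S = diag of preliminary signs) for the adaptive one, since
# beta' L beta = sum_(i,j) w_ij (beta_i/sqrt(d_i) - beta_j/sqrt(d_j))^2.
penalty_quadratic_matrix <- function(L, signs = NULL) {
  if (is.null(signs)) return(L)
  L * tcrossprod(signs)
}

check_lambda_alpha <- function(lambda, alpha) {
  if (!is.numeric(lambda) || lambda <= 0) abort("lambda must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    abort("alpha must lie in (0, 1]")
  }
  invisible(TRUE)
}

weight_signs <- function(weights, p) {
  s <- if (inherits(weights, "adaptive_weights")) weights$signs else weights
  if (length(s) != p) abort("sign vector length does not match beta")
  s
}
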