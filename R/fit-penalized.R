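# Network-penalized Cox solvers. Both minimize
#   F(beta) = -logPL(beta) + lambda*alpha*||beta||_1
#             + lambda*(1-alpha)*beta' Q beta
# on internally standardized columns, where Q is the normalized Laplacian L
# (ADMM variant) or the sign-adapted S L S (adaptive variant). The l1 term
# is handled by soft-thresholding in both algorithms.

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

penalized_objective <- function(beta, xs, oo, Q, lambda, alpha) {
  eta <- drop(xs %*% beta)
  -cox_eta_derivs(eta, oo)$logpl + lambda * alpha * sum(abs(beta)) +
    lambda * (1 - alpha) * drop(crossprod(beta, Q %*% beta))
}

#' Smallest lambda with an all-zero solution
#'
#' The top of the regularization path: since the quadratic network term has
#' zero gradient at the origin, `beta = 0` solves the penalized problem iff
#' `max_j |dl/dbeta_j(0)| <= lambda * alpha`.
#'
#' @param x Patient x gene matrix.
#' @param surv Aligned `survival_data`.
#' @param alpha Network-balance parameter in (0, 1].
#' @param standardize Standardize columns first (the solvers always do).
#' @return `max_j |score_j| / alpha`.
#' @export
lambda_max <- function(x, surv, alpha = 0.5, standardize = TRUE) {
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  check_lambda_alpha(1, alpha)
  if (standardize) x <- standardize_columns(x)$x
  oo <- cox_order(surv$time, surv$event)
  score <- drop(crossprod(x, cox_eta_derivs(numeric(nrow(x)), oo)$grad_eta))
  max(abs(score)) / alpha
}

#' Preliminary coefficients for the adaptive penalty
#'
#' The sign pattern `sgn(beta_tilde)` that the adaptive signed-Laplacian
#' penalty flips coefficients by. `method = "marginal"` uses the per-gene
#' marginal Cox MMLE on standardized columns (deterministic, reuses the
#' screening machinery); `method = "ridge"` fits one l2-penalized Cox model
#' jointly. `sgn(0) := +1` by convention.
#'
#' @param x Patient x gene matrix.
#' @param surv Aligned `survival_data`.
#' @param method `"marginal"` (default) or `"ridge"`.
#' @param lambda_ridge Ridge penalty used by `method = "ridge"`.
#' @return An `adaptive_weights` list with `beta_tilde` and `signs`.
#' @export
make_adaptive_weights <- function(x, surv, method = c("marginal", "ridge"),
                                  lambda_ridge = 1) {
  method <- match.arg(method)
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  xs <- standardize_columns(x)$x
  if (method == "marginal") {
    bt <- marginal_mmle_all(xs, surv)$marginal_beta
  } else {
    bt <- ridge_cox(xs, surv, lambda_ridge)
  }
  s <- sign(bt)
  s[s == 0] <- 1
  structure(list(beta_tilde = setNames(bt, colnames(x)),
                 signs = setNames(s, colnames(x)), method = method),
            class = "adaptive_weights")
}

# Newton solver for -logPL + lambda*||beta||^2 (used for ridge weights)
ridge_cox <- function(xs, surv, lambda, max_iter = 50, tol = 1e-9) {
  oo <- cox_order(surv$time, surv$event)
  p <- ncol(xs)
  beta <- numeric(p)
  obj <- function(b) -cox_eta_derivs(drop(xs %*% b), oo)$logpl +
    lambda * sum(b^2)
  f0 <- obj(beta)
  for (it in seq_len(max_iter)) {
    g <- -cox_grad(beta, xs, oo) + 2 * lambda * beta
    H <- cox_neg_hessian(beta, xs, oo) + diag(2 * lambda, p)
    step <- solve(H + diag(1e-10, p), g)
    t_ls <- 1
    repeat {
      cand <- beta - t_ls * step
      f1 <- obj(cand)
      if (f1 <= f0 + 1e-12 || t_ls < 1e-8) break
      t_ls <- t_ls / 2
    }
    beta <- cand
    if (abs(f0 - f1) < tol * (1 + abs(f1))) break
    f0 <- f1
  }
  beta
}

new_coxnet_fit <- function(beta, genes, lambda, alpha, objective, n_iter,
                           converged, method, center, scale) {
  structure(list(beta = setNames(beta, genes), genes = genes,
                 lambda = lambda, alpha = alpha, objective = objective,
                 n_iter = n_iter, converged = converged, method = method,
                 center = center, scale = scale),
            class = "coxnet_fit")
}

#' @export
print.coxnet_fit <- function(x, ...) {
  cat(sprintf(
    "<coxnet_fit:%s> %d/%d nonzero, lambda=%.4g, alpha=%.2g, obj=%.6g (%s)\n",
    x$method, sum(x$beta != 0), length(x$beta), x$lambda, x$alpha,
    x$objective, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# ---- adaptive signed-Laplacian solver (IRLS + cyclic coordinate descent) --

#' Coordinate-descent solver tolerances
#'
#' @param max_outer Cap on outer (quadratic-approximation) iterations.
#' @param max_cd Cap on coordinate-descent sweeps per outer iteration.
#' @param tol_obj Relative objective-change stopping tolerance.
#' @param tol_cd Coordinate-change stopping tolerance for inner sweeps.
#' @return Control list for [fit_adalnet()].
#' @export
solver_control <- function(max_outer = 200, max_cd = 5000,
                           tol_obj = 1e-11, tol_cd = 1e-10) {
  list(max_outer = max_outer, max_cd = max_cd,
       tol_obj = tol_obj, tol_cd = tol_cd)
}

# core CD solver on prepared (standardized) data
fit_cd_core <- function(xs, oo, Q, lambda, alpha, beta0 = NULL,
                        control = solver_control()) {
  n <- nrow(xs); p <- ncol(xs)
  beta <- beta0 %||% numeric(p)
  twoQ <- 2 * lambda * (1 - alpha) * Q
  obj <- penalized_objective(beta, xs, oo, Q, lambda, alpha)
  trace <- obj
  converged <- FALSE
  it <- 0
  for (outer in seq_len(control$max_outer)) {
    it <- outer
    eta <- drop(xs %*% beta)
    dv <- cox_eta_derivs(eta, oo)
    w <- dv$w
    live <- w > 1e-10
    # working residual r = w*(z - eta) = grad_eta on live observations
    r <- dv$grad_eta
    r[!live] <- 0
    wxx <- colSums(w * xs^2)
    beta_prev <- beta
    cd <- cd_sweeps(xs, w, r, beta, twoQ, wxx, lambda * alpha,
                    control$tol_cd, control$max_cd)
    beta <- cd$beta
    # guard: step-halve toward the previous iterate if the quadratic
    # approximation overshot the true objective
    obj_new <- penalized_objective(beta, xs, oo, Q, lambda, alpha)
    t_ls <- 1
    while (obj_new > obj + 1e-12 && t_ls > 1e-10) {
      t_ls <- t_ls / 2
      beta <- beta_prev + t_ls * (beta - beta_prev)
      obj_new <- penalized_objective(beta, xs, oo, Q, lambda, alpha)
    }
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) < control$tol_obj * (1 + abs(obj_new)) &&
        max(abs(beta - beta_prev)) < 10 * control$tol_cd) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  list(beta = beta, objective = obj, n_iter = it, converged = converged,
       obj_trace = trace)
}

#' Fit the adaptive signed-Laplacian network-penalized Cox model
#'
#' Minimizes `-logPL(beta) + lambda * [alpha * ||beta||_1 + (1 - alpha) *
#' Phi(beta)]` with the sign-adapted, degree-scaled Laplacian smoothness
#' term `Phi` (see [adalnet_penalty()]), by iteratively reweighted least
#' squares with cyclic coordinate descent; every coordinate update is a
#' closed-form soft-threshold. The penalized objective is non-increasing
#' across outer iterations (a step-halving guard enforces descent).
#'
#' @param x Patient x gene matrix (columns are standardized internally).
#' @param surv Aligned `survival_data`.
#' @param net A `gene_network`; genes of `x` absent from it are isolated
#'   (zero-weight completion) and incur only the l1 term.
#' @param lambda Sparsity parameter, > 0.
#' @param alpha Network-balance parameter in (0, 1], default 0.5.
#' @param weights Optional `adaptive_weights`; computed with the marginal
#'   method when omitted.
#' @param beta0 Optional warm start.
#' @param control Solver tolerances, see [solver_control()].
#' @return A `coxnet_fit` (coefficients on the standardized scale, plus the
#'   training centers/scales needed to apply them).
#' @export
fit_adalnet <- function(x, surv, net, lambda, alpha = 0.5, weights = NULL,
                        beta0 = NULL, control = solver_control()) {
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  check_lambda_alpha(lambda, alpha)
  std <- standardize_columns(x)
  weights <- weights %||% make_adaptive_weights(x, surv)
  oo <- cox_order(surv$time, surv$event)
  lb <- normalized_laplacian(net, colnames(x))
  Q <- penalty_quadratic_matrix(lb$L, weight_signs(weights, ncol(x)))
  res <- fit_cd_core(std$x, oo, Q, lambda, alpha, beta0, control)
  if (!res$converged) warn("fit_adalnet did not converge; increase max_outer")
  fit <- new_coxnet_fit(res$beta, colnames(x), lambda, alpha, res$objective,
                        res$n_iter, res$converged, "adalnet",
                        std$center, std$scale)
  fit$obj_trace <- res$obj_trace
  fit
}

# ---- ADMM solver (quadratic Laplacian penalty) ----------------------------

#' ADMM solver settings
#'
#' @param rho Initial augmented-Lagrangian parameter (> 0); adapted during
#'   the run by residual balancing.
#' @param tol_primal,tol_dual Absolute stopping tolerances on the primal
#'   residual `||x - z||` and dual residual `||rho (z - z_old)||`; when
#'   `NULL` they default to `1e-6 * sqrt(d)`.
#' @param max_iter Iteration cap.
#' @return Settings list.
#' @export
admm_settings <- function(rho = 1, tol_primal = NULL, tol_dual = NULL,
                          max_iter = 5000) {
  stopifnot(rho > 0, max_iter >= 1)
  list(rho = rho, tol_primal = tol_primal, tol_dual = tol_dual,
       max_iter = max_iter)
}

#' Fit the quadratic-Laplacian network-penalized Cox model by ADMM
#'
#' Operator splitting of `-logPL(x) + lambda*(1-alpha)*x'Lx` (smooth part
#' `f`) and `lambda*alpha*||z||_1` (`g`) under the constraint `x - z = 0`:
#' the x-update is a Newton minimization of the smooth augmented term, the
#' z-update a soft-threshold, and the dual update
#' `y <- y + rho (x - z)`. The returned coefficients are `z`, so zeros are
#' exact.
#'
#' @inheritParams fit_adalnet
#' @param net_or_L A `gene_network`, a `laplacian_bundle`, or a Laplacian
#'   matrix over the columns of `x`.
#' @param settings See [admm_settings()].
#' @return A `coxnet_fit` with `method = "admmnet"`.
#' @export
fit_admmnet <- function(x, surv, net_or_L, lambda, alpha = 0.5,
                        settings = admm_settings(), beta0 = NULL) {
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  check_lambda_alpha(lambda, alpha)
  std <- standardize_columns(x)
  xs <- std$x
  oo <- cox_order(surv$time, surv$event)
  L <- as_laplacian_matrix(net_or_L, colnames(x))
  n <- nrow(xs); p <- ncol(xs)
  rho <- settings$rho
  tol_p <- settings$tol_primal %||% (1e-6 * sqrt(p))
  tol_d <- settings$tol_dual %||% (1e-6 * sqrt(p))
  xk <- beta0 %||% numeric(p)
  zk <- xk
  u <- numeric(p)                          # scaled dual y / rho
  twoL <- 2 * lambda * (1 - alpha) * L
  smooth_obj <- function(b, target) {
    eta <- drop(xs %*% b)
    -cox_eta_derivs(eta, oo)$logpl +
      0.5 * drop(crossprod(b, twoL %*% b)) +
      (rho / 2) * sum((b - target)^2)
  }
  converged <- FALSE
  iter <- 0
  for (k in seq_len(settings$max_iter)) {
    iter <- k
    target <- zk - u
    # x-update: damped Newton on the smooth augmented objective
    f0 <- smooth_obj(xk, target)
    for (nw in seq_len(50)) {
      g <- -cox_grad(xk, xs, oo) + drop(twoL %*% xk) + rho * (xk - target)
      if (max(abs(g)) < 1e-10 * (1 + rho)) break
      H <- cox_neg_hessian(xk, xs, oo) + twoL + diag(rho, p)
      step <- solve(H + diag(1e-12, p), g)
      t_ls <- 1
      repeat {
        cand <- xk - t_ls * step
        f1 <- smooth_obj(cand, target)
        if (f1 <= f0 + 1e-12 || t_ls < 1e-9) break
        t_ls <- t_ls / 2
      }
      if (f1 > f0) break
      xk <- cand
      if (abs(f0 - f1) < 1e-13 * (1 + abs(f1))) { f0 <- f1; break }
      f0 <- f1
    }
    z_old <- zk
    zk <- soft_threshold(xk + u, lambda * alpha / rho)
    u <- u + xk - zk
    r_primal <- sqrt(sum((xk - zk)^2))
    r_dual <- rho * sqrt(sum((zk - z_old)^2))
    if (r_primal < tol_p && r_dual < tol_d) { converged <- TRUE; break }
    # residual balancing keeps the two residuals within a decade
    if (r_primal > 10 * r_dual) { rho <- rho * 2; u <- u / 2 }
    else if (r_dual > 10 * r_primal) { rho <- rho / 2; u <- u * 2 }
  }
  if (!converged) warn("fit_admmnet did not converge; increase max_iter")
  obj <- penalized_objective(zk, xs, oo, L, lambda, alpha)
  fit <- new_coxnet_fit(zk, colnames(x), lambda, alpha, obj, iter,
                        converged, "admmnet", std$center, std$scale)
  fit$admm_state <- list(x = xk, u = u, rho = rho)
  fit
}

as_laplacian_matrix <- function(net_or_L, genes) {
  if (inherits(net_or_L, "laplacian_bundle")) {
    stopifnot(identical(net_or_L$genes, genes))
    return(net_or_L$L)
  }
  if (is.matrix(net_or_L)) {
    stopifnot(nrow(net_or_L) == length(genes))
    return(net_or_L)
  }
  if (inherits(net_or_L, "gene_network") || is.data.frame(net_or_L)) {
    return(normalized_laplacian(gene_network(net_or_L), genes)$L)
  }
  abort("expected a gene_network, laplacian_bundle or matrix")
}

# ---- regularization path --------------------------------------------------

#' Geometric lambda path from lambda_max
#'
#' @param lmax Top of the path (see [lambda_max()]).
#' @param n_lambda Number of grid points (default 50).
#' @param ratio Smallest lambda as a fraction of `lmax` (default 0.01).
#' @return Decreasing numeric vector.
#' @export
lambda_path <- function(lmax, n_lambda = 50, ratio = 0.01) {
  stopifnot(lmax > 0, n_lambda >= 2, ratio > 0, ratio < 1)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# warm-started path fit used by cross-validation; returns coefficient
# matrix (p x n_lambda) on the standardized scale
fit_path_core <- function(xs, oo, Q, lambdas, alpha,
                          control = solver_control(max_outer = 12,
                                                   max_cd = 80,
                                                   tol_obj = 1e-5,
                                                   tol_cd = 2e-5)) {
  p <- ncol(xs)
  B <- matrix(0, p, length(lambdas))
  beta <- numeric(p)
  for (i in seq_along(lambdas)) {
    res <- fit_cd_core(xs, oo, Q, lambdas[i], alpha, beta0 = beta,
                       control = control)
    beta <- res$beta
    B[, i] <- beta
  }
  B
}
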