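#' Cross-validation settings
#'
#' @param k Number of folds (default 5).
#' @param repeats Fold reshuffles; the selected lambda is averaged across
#'   repeats (default 10).
#' @param alpha Network-balance parameter held fixed during tuning
#'   (default 0.5, moderate network influence).
#' @param seed Integer seed controlling every fold assignment.
#' @param n_lambda,lambda_ratio Geometric lambda grid, from `lambda_max`
#'   down to `lambda_ratio * lambda_max`.
#' @param stratify_events Spread events evenly across folds so no fold is
#'   event-free (default TRUE); plain randomization otherwise.
#' @return Settings list.
#' @export
cv_settings <- function(k = 5, repeats = 10, alpha = 0.5, seed = 1,
                        n_lambda = 50, lambda_ratio = 0.01,
                        stratify_events = TRUE) {
  stopifnot(k >= 2, repeats >= 1)
  list(k = k, repeats = repeats, alpha = alpha, seed = as.integer(seed),
       n_lambda = n_lambda, lambda_ratio = lambda_ratio,
       stratify_events = stratify_events)
}

#' Fold assignment as a partition of patients
#'
#' Every patient lands in exactly one fold; fold sizes differ by at most
#' one. With `stratify_events`, events and censored records are shuffled
#' and dealt round-robin separately.
#'
#' @param surv A `survival_data` tibble.
#' @param k Number of folds.
#' @param stratify_events Stratified assignment (default TRUE).
#' @return Integer vector of fold labels in 1..k.
#' @export
make_folds <- function(surv, k, stratify_events = TRUE) {
  n <- nrow(surv)
  stopifnot(k >= 2, k <= n)
  folds <- integer(n)
  if (stratify_events) {
    # deal strata round-robin with a continuing offset so overall fold
    # sizes differ by at most one
    offset <- 0L
    for (grp in list(which(surv$event == 1), which(surv$event == 0))) {
      if (length(grp) > 0) {
        folds[sample(grp)] <-
          ((offset + seq_along(grp) - 1L) %% k) + 1L
        offset <- offset + length(grp)
      }
    }
  } else {
    folds[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  folds
}

# log partial likelihood of a fitted standardized-scale beta on arbitrary
# data, using the fit's training centers/scales
logpl_on <- function(beta, center, scale, x, surv) {
  eta <- drop(sweep(sweep(x, 2, center), 2, scale, "/") %*% beta)
  oo <- cox_order(surv$time, surv$event)
  cox_eta_derivs(eta, oo)$logpl
}

#' Cross-validated partial likelihood for one lambda
#'
#' The van Houwelingen form: `CVPL = (1/n) sum_k [l(beta^(-k)) -
#' l^(-k)(beta^(-k))]`, where `l` is the Cox log partial likelihood on all
#' samples, `l^(-k)` on the data with fold `k` removed, and `beta^(-k)` is
#' fitted without fold `k`. Larger is better; lambda is chosen by
#' maximizing this quantity. (Some write-ups print the same display with a
#' leading minus sign while still selecting the maximizer of the
#' cross-validated likelihood contribution; this package keeps the
#' to-be-maximized orientation.)
#'
#' @param x Patient x gene matrix.
#' @param surv Aligned `survival_data`.
#' @param net A `gene_network` over the columns of `x`.
#' @param method `"adalnet"` or `"admmnet"`.
#' @param lambda,alpha Penalty parameters.
#' @param folds Integer fold labels (see [make_folds()]); every fold must
#'   contain at least one event.
#' @return CVPL (scalar, to be maximized).
#' @export
cvpl <- function(x, surv, net, method = c("adalnet", "admmnet"),
                 lambda, alpha = 0.5, folds) {
  method <- match.arg(method)
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  check_folds(folds, surv)
  n <- nrow(x)
  total <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k
    x_tr <- x[tr, , drop = FALSE]
    s_tr <- surv[tr, , drop = FALSE]
    fit <- if (method == "adalnet") {
      fit_adalnet(x_tr, s_tr, net, lambda, alpha,
                  control = solver_control(max_outer = 50, tol_obj = 1e-9,
                                           tol_cd = 1e-9))
    } else {
      fit_admmnet(x_tr, s_tr, net, lambda, alpha)
    }
    l_full <- logpl_on(fit$beta, fit$center, fit$scale, x, surv)
    l_tr <- logpl_on(fit$beta, fit$center, fit$scale, x_tr, s_tr)
    total <- total + (l_full - l_tr)
  }
  total / n
}

check_folds <- function(folds, surv) {
  stopifnot(length(folds) == nrow(surv))
  ev <- tapply(surv$event, folds, sum)
  if (any(ev == 0)) {
    abort("a fold contains no events; re-randomize the fold assignment",
          class = "screennet_validation_error")
  }
  invisible(TRUE)
}

#' Select lambda by repeated K-fold cross-validated partial likelihood
#'
#' For each repeat, folds are reshuffled (seeded), the CVPL is computed on
#' a warm-started lambda path for every fold, and the per-repeat maximizer
#' is recorded. The final estimate is the arithmetic mean of the
#' per-repeat maximizers, snapped to the nearest grid point. Alpha stays
#' fixed throughout (default 0.5).
#'
#' Path fits for both methods run through the coordinate-descent engine on
#' the method's own objective (the two solvers target the same optimum;
#' the final refit uses the requested algorithm).
#'
#' @param x Patient x gene matrix.
#' @param surv Aligned `survival_data`.
#' @param net A `gene_network`.
#' @param method `"adalnet"` or `"admmnet"`.
#' @param settings See [cv_settings()].
#' @param weights Optional `adaptive_weights` for the adalnet objective;
#'   recomputed on each training fold when omitted.
#' @return A `cv_lambda` object: `cvpl_by_lambda` (repeats x grid),
#'   `lambda_grid`, `lambda_hat_per_repeat`, `lambda_hat`,
#'   `fold_assignments`.
#' @export
select_lambda <- function(x, surv, net, method = c("adalnet", "admmnet"),
                          settings = cv_settings(), weights = NULL) {
  method <- match.arg(method)
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  lmax <- lambda_max(x, surv, settings$alpha)
  grid <- lambda_path(lmax, settings$n_lambda, settings$lambda_ratio)
  lb <- normalized_laplacian(net, colnames(x))
  n <- nrow(x)
  fold_list <- withr::with_seed(settings$seed, {
    lapply(seq_len(settings$repeats), function(r) {
      make_folds(surv, settings$k, settings$stratify_events)
    })
  })
  cv_mat <- matrix(NA_real_, settings$repeats, length(grid))
  for (r in seq_len(settings$repeats)) {
    folds <- fold_list[[r]]
    check_folds(folds, surv)
    contrib <- numeric(length(grid))
    for (k in sort(unique(folds))) {
      tr <- folds != k
      x_tr <- x[tr, , drop = FALSE]
      s_tr <- surv[tr, , drop = FALSE]
      std <- standardize_columns(x_tr)
      Q <- if (method == "adalnet") {
        w <- weights %||% make_adaptive_weights(x_tr, s_tr)
        penalty_quadratic_matrix(lb$L, weight_signs(w, ncol(x)))
      } else {
        lb$L
      }
      oo_tr <- cox_order(s_tr$time, s_tr$event)
      B <- fit_path_core(std$x, oo_tr, Q, grid, settings$alpha)
      for (i in seq_along(grid)) {
        l_full <- logpl_on(B[, i], std$center, std$scale, x, surv)
        l_tr <- logpl_on(B[, i], std$center, std$scale, x_tr, s_tr)
        contrib[i] <- contrib[i] + (l_full - l_tr)
      }
    }
    cv_mat[r, ] <- contrib / n
  }
  lam_r <- grid[apply(cv_mat, 1, which.max)]
  lam_mean <- mean(lam_r)
  lambda_hat <- grid[which.min(abs(grid - lam_mean))]
  structure(list(cvpl_by_lambda = cv_mat, lambda_grid = grid,
                 lambda_hat_per_repeat = lam_r, lambda_hat = lambda_hat,
                 lambda_mean = lam_mean, fold_assignments = fold_list,
                 alpha = settings$alpha, method = method,
                 settings = settings),
            class = "cv_lambda")
}

#' @export
print.cv_lambda <- function(x, ...) {
  cat(sprintf(
    "<cv_lambda:%s> %d-fold x %d repeat(s); lambda_hat = %.5g (grid %.3g..%.3g)\n",
    x$method, x$settings$k, x$settings$repeats, x$lambda_hat,
    min(x$lambda_grid), max(x$lambda_grid)))
  invisible(x)
}
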