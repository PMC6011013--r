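test_that("log partial likelihood matches closed forms and shift invariance", {
  surv <- surv3()
  x <- x3()
  expect_equal(cox_logpl(0, x, surv), -log(6), tolerance = 1e-12)
  # hand evaluation at the MMLE: b - log(2 e^b + 1) - log(1 + e^b)
  b <- -log(2) / 2
  expect_equal(cox_logpl(b, x, surv),
               b - log(2 * exp(b) + 1) - log(1 + exp(b)),
               tolerance = 1e-12)
  # shifting a covariate cancels inside risk-set ratios
  expect_equal(cox_logpl(0.7, x + 5, surv), cox_logpl(0.7, x, surv),
               tolerance = 1e-10)
})

test_that("log partial likelihood agrees with naive risk-set loops under ties", {
  withr::local_seed(5)
  for (rep in 1:20) {
    n <- 25
    surv <- survival_data(data.frame(
      patient_id = sprintf("p%02d", 1:n),
      time = sample(1:8, n, replace = TRUE),   # heavy ties
      event = rbinom(n, 1, 0.7)))
    if (sum(surv$event) == 0) surv$event[1] <- 1L
    x <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(surv$patient_id, c("a", "b", "c")))
    beta <- rnorm(3)
    expect_equal(cox_logpl(beta, x, surv),
                 naive_logpl(beta, x, surv$time, surv$event),
                 tolerance = 1e-10)
  }
})

test_that("network penalties reproduce hand-computed fixture values", {
  net <- two_node_net()
  genes <- c("A", "B")
  expect_equal(adalnet_penalty(c(1, 1), c(1, 1), net, genes, 1, 0.5), 1)
  # sign adaptivity absorbs opposite-sign neighbours
  expect_equal(adalnet_penalty(c(1, -1), c(1, -1), net, genes, 1, 0.5), 1)
  expect_equal(adalnet_penalty(c(1, -1), c(1, 1), net, genes, 1, 0.5), 3)

  L <- normalized_laplacian(net, genes)$L
  expect_equal(quad_laplacian_penalty(c(0, 0), L, 1, 0.5), 0)
  expect_equal(quad_laplacian_penalty(c(1, -1), L, 1, 0.5), 3)
  expect_equal(quad_laplacian_penalty(c(1, -1), L, 2, 1), 4)  # pure l1
})

test_that("adaptive smooth term vanishes when degree-scaled betas align", {
  net <- gene_network(data.frame(from = c("A", "B", "A"),
                                 to = c("B", "C", "C"), weight = 1))
  genes <- c("A", "B", "C")
  beta <- c(2, -2, 2)          # equal degrees, equal |beta|, signs = beta
  pen <- adalnet_penalty(beta, sign(beta), net, genes, 1, 0.5)
  expect_equal(pen, 0.5 * sum(abs(beta)))
})

test_that("lambda_max scales with alpha and equals the score bound", {
  sim <- small_cohort(seed = 3)
  x <- sim$expression; surv <- sim$survival
  expect_equal(lambda_max(x, surv, 1) * 2, lambda_max(x, surv, 0.5),
               tolerance = 1e-12)
  # hand gradient of the partial likelihood at zero on standardized columns
  score <- naive_grad(numeric(5), scale(x), surv$time, surv$event)
  expect_equal(lambda_max(x, surv, 0.5), max(abs(score)) / 0.5,
               tolerance = 1e-10)
  # permutation invariance
  perm <- sample(nrow(x))
  expect_equal(lambda_max(x[perm, ], surv[perm, ], 0.5),
               lambda_max(x, surv, 0.5), tolerance = 1e-10)
})

test_that("lambda >= lambda_max gives exactly zero for both solvers", {
  sim <- small_cohort(seed = 9)
  lmax <- lambda_max(sim$expression, sim$survival, 0.5)
  fa <- fit_adalnet(sim$expression, sim$survival, sim$network, lmax * 1.0001,
                    0.5)
  fm <- fit_admmnet(sim$expression, sim$survival, sim$network, lmax * 1.0001,
                    0.5)
  expect_identical(unname(fa$beta), numeric(5))
  expect_identical(unname(fm$beta), numeric(5))
})

test_that("both solvers attain the proximal-oracle objective", {
  sim <- small_cohort(seed = 1)
  x <- sim$expression; surv <- sim$survival
  w <- make_adaptive_weights(x, surv)
  lb <- normalized_laplacian(sim$network, colnames(x))
  lam <- 0.1 * lambda_max(x, surv, 0.5)
  fa <- fit_adalnet(x, surv, sim$network, lam, 0.5, weights = w)
  fm <- fit_admmnet(x, surv, sim$network, lam, 0.5)
  xs <- scale(x)
  Qa <- lb$L * tcrossprod(w$signs)
  oa <- fista_oracle(xs, surv$time, surv$event, Qa, lam, 0.5)
  om <- fista_oracle(xs, surv$time, surv$event, lb$L, lam, 0.5)
  expect_lt(abs(fa$objective - oa$objective) / max(1, abs(oa$objective)),
            1e-6)
  expect_lt(abs(fm$objective - om$objective) / max(1, abs(om$objective)),
            1e-6)
  expect_lt(max(abs(fa$beta - oa$beta)), 1e-4)
  expect_lt(max(abs(fm$beta - om$beta)), 1e-4)
  expect_true(fa$converged)
  expect_true(fm$converged)
})

test_that("at alpha = 1 both solvers agree with the glmnet Cox lasso", {
  sim <- small_cohort(seed = 2)
  x <- sim$expression; surv <- sim$survival
  n <- nrow(x)
  lam <- 0.15 * lambda_max(x, surv, 1)
  fa <- fit_adalnet(x, surv, sim$network, lam, 1)
  fm <- fit_admmnet(x, surv, sim$network, lam, 1)
  expect_lt(max(abs(fa$beta - fm$beta)), 1e-4)
  # independent library cross-check: glmnet minimizes -(1/n) logpl +
  # lambda ||beta||_1 on the given matrix, so lambda_glmnet = lambda / n
  gn <- glmnet::glmnet(scale(x), survival::Surv(surv$time, surv$event),
                       family = "cox", lambda = lam / n,
                       standardize = FALSE, thresh = 1e-14)
  expect_lt(max(abs(fa$beta - as.vector(gn$beta))), 1e-4)
})

test_that("the penalized objective is non-increasing across outer iterations", {
  for (seed in c(4, 5)) {
    sim <- small_cohort(seed = seed)
    lam <- 0.05 * lambda_max(sim$expression, sim$survival, 0.5)
    fit <- fit_adalnet(sim$expression, sim$survival, sim$network, lam, 0.5)
    expect_true(all(diff(fit$obj_trace) <= 1e-8))
  }
})

test_that("ADMM reaches primal feasibility at convergence", {
  sim <- small_cohort(seed = 6)
  lam <- 0.1 * lambda_max(sim$expression, sim$survival, 0.5)
  fit <- fit_admmnet(sim$expression, sim$survival, sim$network, lam, 0.5)
  expect_true(fit$converged)
  expect_lt(sqrt(sum((fit$admm_state$x - fit$beta)^2)), 1e-6 * sqrt(5))
})

test_that("support grows down the regularization path", {
  sim <- small_cohort(seed = 8)
  lmax <- lambda_max(sim$expression, sim$survival, 0.5)
  grid <- lambda_path(lmax, 8, 0.02)
  nnz <- sapply(grid, function(l) {
    sum(fit_adalnet(sim$expression, sim$survival, sim$network, l, 0.5,
                    control = solver_control(max_outer = 50,
                                             tol_obj = 1e-9,
                                             tol_cd = 1e-8))$beta != 0)
  })
  expect_equal(nnz[1], 0)                 # empty support at lambda_max
  expect_gte(nnz[length(nnz)], nnz[1])
  expect_gt(nnz[length(nnz)], 0)
})

test_that("adaptive weights recover planted signs and flag degeneracy", {
  hits <- 0
  for (seed in 1:5) {
    sim <- small_cohort(seed = seed + 100, n = 500, p = 5, support = 1,
                        beta_true = 1)
    w <- make_adaptive_weights(sim$expression, sim$survival)
    hits <- hits + (w$signs[1] == 1)
  }
  expect_gte(hits, 4)

  x <- cbind(x3(), const = 1)
  colnames(x) <- c("g1", "g2")
  w <- make_adaptive_weights(x, surv3())
  expect_equal(unname(w$beta_tilde["g2"]), 0)
  expect_equal(unname(w$signs["g2"]), 1)   # sgn(0) := +1

  # ridge alternative is finite and sign-consistent on strong signal
  simr <- small_cohort(seed = 300, n = 300, p = 5, support = 1,
                       beta_true = 1.5)
  wr <- make_adaptive_weights(simr$expression, simr$survival,
                              method = "ridge")
  expect_true(all(is.finite(wr$beta_tilde)))
  expect_equal(unname(wr$signs[1]), 1)
})
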