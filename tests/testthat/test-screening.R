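test_that("marginal MMLE matches the closed-form three-patient solution", {
  m <- marginal_cox_mmle(c(1, 0, 1), surv3())
  expect_false(m$degenerate)
  expect_equal(m$beta, -log(2) / 2, tolerance = 1e-6)
  # agreement with an independent numeric maximization of the naive logpl
  expect_equal(m$beta, numeric_mmle(c(1, 0, 1), c(1, 2, 3), c(1, 1, 1)),
               tolerance = 1e-6)
})

test_that("degenerate marginal fits are flagged, not returned as estimates", {
  expect_identical(marginal_cox_mmle(c(2, 2, 2), surv3()),
                   list(beta = 0, degenerate = TRUE))
  # monotone likelihood: event first for the x = 1 patient
  s2 <- survival_data(data.frame(patient_id = c("a", "b"),
                                 time = c(1, 2), event = c(1, 1)))
  m <- marginal_cox_mmle(c(1, 0), s2)
  expect_true(m$degenerate)
  # oracle confirmation: the naive log-likelihood increases over a beta grid
  grid <- seq(0, 14, by = 2)
  ll <- sapply(grid, function(b) naive_logpl(b, matrix(c(1, 0)), c(1, 2),
                                             c(1, 1)))
  expect_true(all(diff(ll) > 0))

  s0 <- survival_data(data.frame(patient_id = 1:3, time = 1:3, event = 0))
  expect_error(marginal_cox_mmle(c(1, 0, 1), s0), "no events")
})

test_that("BMD screening keeps p <= 0.05 genes measured in the matrix", {
  tab <- data.frame(gene = c("A", "B", "C", "Z"),
                    assoc_p = c(0.01, 0.05, 0.06, 0.001))
  res <- bmd_screen(tab, genes = c("A", "B", "C"))
  expect_setequal(res$gene, c("A", "B"))    # inclusive cutoff; Z unmeasured
  expect_identical(attr(res, "kind"), "BMD")

  expect_warning(
    empty <- bmd_screen(data.frame(gene = character(), assoc_p = double()),
                        genes = c("A", "B")),
    "no genes")
  expect_equal(nrow(empty), 0)
})

test_that("default DAD size is floor(n log n)", {
  expect_identical(default_dad_size(100), 460L)
  expect_identical(default_dad_size(3), 3L)
  expect_identical(default_dad_size(2), 1L)
  expect_error(default_dad_size(1))
})

test_that("DAD screening ranks genes by independently computed |MMLE|", {
  sim <- small_cohort(seed = 2, n = 80, p = 6, support = c(1, 3),
                      beta_true = c(1.2, -1))
  x <- sim$expression; surv <- sim$survival
  xs <- scale(x)
  oracle_beta <- sapply(seq_len(ncol(x)), function(j) {
    numeric_mmle(xs[, j], surv$time, surv$event)
  })
  oracle_rank <- order(abs(oracle_beta), decreasing = TRUE)
  res <- dad_screen(x, surv, 3)
  expect_identical(res$gene[1:3], colnames(x)[oracle_rank[1:3]])
  expect_equal(attr(res, "threshold_used"),
               sort(abs(oracle_beta), decreasing = TRUE)[3],
               tolerance = 1e-5)
  # d_dad = p keeps everything
  expect_setequal(dad_screen(x, surv, 6)$gene, colnames(x))
  expect_error(dad_screen(x, surv, 0), "positive")
  expect_error(dad_screen(x, surv, 7), "exceeds")
})

test_that("increasing d_dad yields nested screened sets", {
  sim <- small_cohort(seed = 7, n = 100, p = 12, support = c(1, 2),
                      beta_true = c(1, -1))
  sets <- lapply(c(2, 4, 8, 12), function(d) {
    dad_screen(sim$expression, sim$survival, d)$gene
  })
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("screened membership is invariant to affine column rescaling", {
  sim <- small_cohort(seed = 12, n = 80, p = 6)
  x2 <- sim$expression
  x2[, 2] <- 5 * x2[, 2] + 3
  a <- dad_screen(sim$expression, sim$survival, 3)$gene
  b <- dad_screen(x2, sim$survival, 3)$gene
  expect_identical(a, b)
})

test_that("union screening is a commutative, idempotent set union", {
  sim <- small_cohort(seed = 4, n = 60, p = 8, support = 1, beta_true = 1)
  dad <- dad_screen(sim$expression, sim$survival, 4)
  tab <- data.frame(gene = c(dad$gene[1], "g0006", "g0007"),
                    assoc_p = c(0.01, 0.02, 0.03))
  bmd <- bmd_screen(tab, colnames(sim$expression))
  u1 <- union_screen(bmd, dad)
  u2 <- union_screen(dad, bmd)
  expect_setequal(u1$gene, union(bmd$gene, dad$gene))
  expect_setequal(u1$gene, u2$gene)
  expect_identical(attr(u1, "kind"), "BMD+DAD")
  expect_setequal(union_screen(u1, u1)$gene, u1$gene)
  # marginal statistics survive the union for the DAD members
  expect_equal(sum(!is.na(u1$marginal_beta)), nrow(dad))

  other <- bmd_screen(tab, genes = c("x1", "x2", "g0006", "g0007"))
  expect_error(union_screen(dad, other), "universes",
               class = "screennet_validation_error")

  suppressWarnings(
    empty <- bmd_screen(data.frame(gene = "zz", assoc_p = 0.01),
                        colnames(sim$expression)))
  expect_setequal(union_screen(dad, empty)$gene, dad$gene)
})

test_that("strong planted signals survive data-driven screening", {
  hits <- 0
  for (seed in 1:2) {
    cfg <- sim_config(n = 500, p = 200, support = c(1, 11, 21, 31, 41),
                      beta_true = rep(0.8, 5), target_censoring = 0.3,
                      seed = seed)
    sim <- simulate_dataset(cfg)
    kept <- dad_screen(sim$expression, sim$survival, 20)$gene
    hits <- hits + all(sprintf("g%04d", c(1, 11, 21, 31, 41)) %in% kept)
  }
  expect_equal(hits, 2)
})
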