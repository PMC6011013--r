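test_that("the prognostic index is the standardized linear score", {
  m0 <- risk_model(genes = "g1", beta = 0, train_means = 0, train_sds = 1)
  x <- matrix(rnorm(4), 4, 1, dimnames = list(paste0("p", 1:4), "g1"))
  expect_equal(unname(prognostic_index(x, m0)), rep(0, 4))

  m1 <- risk_model(genes = "g1", beta = 2, train_means = 1, train_sds = 2)
  x1 <- matrix(4, 1, 1, dimnames = list("p1", "g1"))  # z = 1.5 -> PI = 3
  expect_equal(unname(prognostic_index(x1, m1)), 3)

  # additivity over disjoint gene sets
  x2 <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("p", 1:5),
                                                c("g1", "g2")))
  ma <- risk_model("g1", 1.5, 0.2, 1.1)
  mb <- risk_model("g2", -0.7, -0.1, 0.9)
  mab <- risk_model(c("g1", "g2"), c(1.5, -0.7), c(0.2, -0.1), c(1.1, 0.9))
  expect_equal(prognostic_index(x2, mab),
               prognostic_index(x2, ma) + prognostic_index(x2, mb))

  expect_error(prognostic_index(x1, mab), "absent.*g2",
               class = "screennet_validation_error")
})

test_that("Kaplan-Meier matches hand products and the textbook oracle", {
  s <- survival_data(data.frame(patient_id = 1:3, time = c(1, 2, 3),
                                event = c(1, 0, 1)))
  km <- kaplan_meier(s)
  expect_equal(km$survival, c(2 / 3, 0))
  expect_equal(km$time, c(1, 3))

  s_none <- survival_data(data.frame(patient_id = 1:3, time = 1:3, event = 0))
  expect_equal(nrow(kaplan_meier(s_none)), 0)    # survival stays 1

  s2 <- survival_data(data.frame(patient_id = 1:2, time = c(2, 5), event = 1))
  expect_equal(kaplan_meier(s2)$survival, c(0.5, 0))

  withr::local_seed(31)
  for (rep in 1:50) {
    surv <- random_surv(sample(5:40, 1))
    km <- kaplan_meier(surv)
    oracle <- textbook_km(surv$time, surv$event)
    expect_equal(km$time, oracle$time)
    expect_equal(km$survival, oracle$survival, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))
    expect_true(all(diff(km$at_risk) <= 0))
  }
})

test_that("log-rank matches the hand-computed fixture and the oracle", {
  s <- survival_data(data.frame(patient_id = 1:3, time = c(1, 2, 3),
                                event = 1))
  lr <- logrank_test(s, c("A", "A", "B"))
  expect_equal(lr$chi2, 25 / 17, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(25 / 17, 1, lower.tail = FALSE))

  # identical survival patterns in the two groups: no separation
  s2 <- survival_data(data.frame(patient_id = 1:6,
                                 time = rep(c(1, 2, 3), 2),
                                 event = rep(c(1, 0, 1), 2)))
  lr2 <- logrank_test(s2, rep(c("A", "B"), each = 3))
  expect_equal(lr2$chi2, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1)

  expect_error(logrank_test(s, c("A", "A", "A")), "two",
               class = "screennet_validation_error")

  withr::local_seed(37)
  for (rep in 1:20) {
    surv <- random_surv(30)
    grp <- rbinom(30, 1, 0.5) == 1
    if (length(unique(grp)) < 2) next
    expect_equal(logrank_test(surv, grp)$chi2,
                 textbook_logrank_chi2(surv$time, surv$event, grp),
                 tolerance = 1e-10)
    # relabeling groups leaves the statistic unchanged
    expect_equal(logrank_test(surv, !grp)$chi2,
                 logrank_test(surv, grp)$chi2, tolerance = 1e-12)
  }
})

test_that("the cutoff scan covers 13 quantile levels and minimizes p", {
  expect_equal(gamma_grid(), seq(0.20, 0.80, 0.05))
  expect_length(gamma_grid(), 13)

  withr::local_seed(41)
  n <- 120
  pi_tr <- rnorm(n)
  # perfectly separated: the top 30% die first
  high <- pi_tr > quantile(pi_tr, 0.7)
  surv <- survival_data(data.frame(
    patient_id = seq_len(n),
    time = ifelse(high, runif(n, 1, 5), runif(n, 20, 40)),
    event = 1))
  oc <- optimal_cutoff(pi_tr, surv)
  expect_equal(oc$p_star, min(oc$scan$p, na.rm = TRUE))
  expect_equal(oc$gamma_star, 0.70)
  expect_equal(oc$pi_star, unname(quantile(pi_tr, 0.70)))

  # log-rank p at the split is invariant to monotone PI transforms
  oc2 <- optimal_cutoff(exp(pi_tr), surv)
  expect_equal(oc2$gamma_star, oc$gamma_star)
  expect_equal(oc2$scan$chi2, oc$scan$chi2, tolerance = 1e-10)

  expect_error(optimal_cutoff(rep(1, n), surv), "degenerate",
               class = "screennet_validation_error")
})

test_that("ties in the scan break toward the smaller gamma", {
  # two-point PI: every gamma below/above the jump gives identical splits
  pi_tr <- rep(c(0, 1), each = 10)
  surv <- survival_data(data.frame(
    patient_id = 1:20,
    time = c(seq(30, 39), seq(1, 10)),
    event = 1))
  oc <- optimal_cutoff(pi_tr, surv)
  tied <- oc$scan$gamma[!is.na(oc$scan$p) &
                          abs(oc$scan$p - oc$p_star) < 1e-12]
  expect_equal(oc$gamma_star, min(tied))
})

test_that("test-set evaluation reuses the frozen training decision rule", {
  sim <- small_cohort(seed = 207, n = 200, p = 5, support = c(1, 2),
                      beta_true = c(1.2, -1))
  x <- sim$expression; surv <- sim$survival
  fit <- fit_adalnet(x, surv, sim$network,
                     0.05 * lambda_max(x, surv, 0.5), 0.5)
  model <- as_risk_model(fit)
  expect_gt(length(model$genes), 0)
  model <- calibrate_cutoff(model, x, surv)
  expect_true(model$gamma_star %in% gamma_grid())

  # evaluating on the training set reproduces the training split
  ev <- evaluate_testset(x, surv, model)
  pi_tr <- prognostic_index(x, model)
  expect_identical(ev$groups$group,
                   ifelse(pi_tr > model$pi_star, "high", "low"))
  expect_true(ev$evaluable)

  # null signature: constant PI, non-evaluable
  m0 <- risk_model("g0001", 0, 0, 1, pi_star = 0)
  ev0 <- evaluate_testset(x, surv, m0)
  expect_false(ev0$evaluable)
  expect_null(ev0$logrank)
})

test_that("cutoff selection never reads test data", {
  sim <- small_cohort(seed = 208, n = 300, p = 5, support = c(1, 2),
                      beta_true = c(1.2, -1))
  tr <- 1:150; te <- 151:300
  x_tr <- sim$expression[tr, ]; s_tr <- sim$survival[tr, ]
  fit <- fit_adalnet(x_tr, s_tr, sim$network,
                     0.05 * lambda_max(x_tr, s_tr, 0.5), 0.5)
  model <- calibrate_cutoff(as_risk_model(fit), x_tr, s_tr)
  # scrambling test outcomes cannot change the fitted rule
  s_te <- sim$survival[te, ]
  s_te_scrambled <- s_te
  s_te_scrambled$time <- rev(s_te$time)
  ev1 <- evaluate_testset(sim$expression[te, ], s_te, model)
  ev2 <- evaluate_testset(sim$expression[te, ], s_te_scrambled, model)
  expect_identical(ev1$groups$group, ev2$groups$group)
  expect_identical(model$pi_star,
                   calibrate_cutoff(as_risk_model(fit), x_tr, s_tr)$pi_star)
})
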