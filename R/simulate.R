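#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the data model the analysis assumes: censored
#' proportional-hazards survival with a constant baseline hazard, gene
#' expression organized in equicorrelated modules matching a weighted
#' module network, a sparse planted coefficient vector, an integer-coded
#' copy-number matrix correlated with expression, and partial biomedical
#' annotation consistent with the planted signal.
#'
#' @param n Patients (default 300 per arm of a typical benchmark cohort).
#' @param p Genes (default 200).
#' @param n_modules,module_size Correlated gene blocks; modules occupy the
#'   first `n_modules * module_size` gene indices, remaining genes are
#'   independent background.
#' @param support Indices of causal genes (default: the first gene of each
#'   of the first five modules, so the signal is network-concordant).
#' @param beta_true Effect sizes for `support` (default all 1: a strong
#'   planted signal, hazard ratio e per SD).
#' @param rho_within Within-module equicorrelation in `[0, 1)`, default
#'   0.6; also the weight of every within-module network edge.
#' @param baseline_hazard Constant baseline hazard `h0 > 0` per month
#'   (default 0.1, i.e. 10-month mean baseline survival).
#' @param censor_max Upper bound of the uniform censoring time; when
#'   `NULL` it is calibrated so the expected censoring fraction equals
#'   `target_censoring`.
#' @param target_censoring Expected censoring fraction used when
#'   `censor_max` is `NULL` (default 0.30).
#' @param cna_concordance Probability a CNA code is derived from the
#'   expression z-score rather than independent noise (default 0.8).
#' @param assoc_causal_frac Fraction of causal genes given a significant
#'   association p-value (< 0.05), emulating partial biomedical knowledge
#'   (default 0.6).
#' @param assoc_coverage Fraction of the remaining genes covered by the
#'   association table at all (default 0.8).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n = 300, p = 200, n_modules = 10, module_size = 10,
                       support = NULL, beta_true = NULL, rho_within = 0.6,
                       baseline_hazard = 0.1, censor_max = NULL,
                       target_censoring = 0.30, cna_concordance = 0.8,
                       assoc_causal_frac = 0.6, assoc_coverage = 0.8,
                       seed = 1) {
  stopifnot(n >= 2, p >= 1, n_modules >= 0, module_size >= 1,
            n_modules * module_size <= p,
            rho_within >= 0, rho_within < 1, baseline_hazard > 0,
            cna_concordance >= 0, cna_concordance <= 1)
  support <- support %||%
    ((seq_len(min(5, max(n_modules, 1))) - 1) * module_size + 1)
  support <- as.integer(support)
  beta_true <- beta_true %||% rep(1, length(support))
  if (length(support) != length(beta_true)) {
    abort("support and beta_true must have the same length")
  }
  if (length(support) > 0 && (min(support) < 1 || max(support) > p)) {
    abort("support indices must lie in 1..p")
  }
  if (anyDuplicated(support)) abort("support indices must be unique")
  if (!is.null(censor_max) && censor_max <= 0) {
    abort("censor_max must be positive")
  }
  structure(list(n = n, p = p, n_modules = n_modules,
                 module_size = module_size, support = support,
                 beta_true = as.double(beta_true), rho_within = rho_within,
                 baseline_hazard = baseline_hazard, censor_max = censor_max,
                 target_censoring = target_censoring,
                 cna_concordance = cna_concordance,
                 assoc_causal_frac = assoc_causal_frac,
                 assoc_coverage = assoc_coverage,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# variance of the planted linear predictor under the block-equicorrelated
# design (unit variances; genes in one module share correlation rho)
linear_predictor_sd <- function(config) {
  if (length(config$support) == 0) return(0)
  mod_of <- module_index(config$support, config)
  v <- 0
  for (m in unique(mod_of)) {
    b <- config$beta_true[mod_of == m]
    if (is.na(m)) {
      v <- v + sum(b^2)                  # background genes: independent
    } else {
      v <- v + sum(b^2) + config$rho_within * (sum(b)^2 - sum(b^2))
    }
  }
  sqrt(v)
}

module_index <- function(gene_idx, config) {
  m <- ceiling(gene_idx / config$module_size)
  m[gene_idx > config$n_modules * config$module_size] <- NA_integer_
  m
}

#' Calibrate the uniform censoring bound to a target censoring fraction
#'
#' Solves for `censor_max` such that `P(T > C)` equals `target_fraction`
#' under the generator's model (`T` exponential given the linear
#' predictor, `C ~ U(0, censor_max)`), by Monte-Carlo root finding with
#' common random numbers at `n_mc` draws.
#'
#' @param config A `sim_config` (its hazard, effect sizes and correlation
#'   structure determine the event-time distribution).
#' @param target_fraction Desired censoring fraction, strictly in (0, 1).
#' @param n_mc Monte-Carlo sample size (default 1e5, accurate to ~0.02).
#' @return The calibrated `censor_max` (scalar).
#' @export
calibrate_censoring <- function(config, target_fraction, n_mc = 1e5) {
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1) {
    abort("target_fraction must lie strictly in (0, 1)")
  }
  if (target_fraction >= 0.99) {
    warn("target censoring >= 0.99: almost every record will be censored")
  }
  sd_eta <- linear_predictor_sd(config)
  draws <- withr::with_seed(config$seed, {
    eta <- if (sd_eta > 0) rnorm(n_mc, 0, sd_eta) else numeric(n_mc)
    list(t = -log(runif(n_mc)) / (config$baseline_hazard * exp(eta)),
         v = runif(n_mc))
  })
  cens_frac <- function(m) mean(draws$t > m * draws$v)
  lo <- 1e-8
  hi <- 1
  while (cens_frac(hi) > target_fraction && hi < 1e12) hi <- hi * 2
  if (cens_frac(hi) > target_fraction) {
    abort("target censoring fraction unattainable")
  }
  uniroot(function(m) cens_frac(m) - target_fraction, c(lo, hi),
          tol = 1e-8)$root
}

#' Simulate a full synthetic cohort
#'
#' Expression rows are zero-mean unit-variance with equicorrelation
#' `rho_within` inside each module and independence across modules
#' (one-factor construction); survival times are
#' `T = -log(U) / (h0 exp(x' beta_true))` with `U ~ U(0,1)` and uniform
#' independent censoring `C ~ U(0, censor_max)`; the network connects all
#' within-module pairs at weight `rho_within`; the association table gives
#' `assoc_p < 0.05` to a seeded subset of causal genes and `>= 0.05` or
#' absence to the rest; each module carries one pathway id; CNA codes are
#' 5-bin thresholded noisy copies of the expression z-scores. Identical
#' configs (same seed) give bit-identical output.
#'
#' @param config A `sim_config`.
#' @return List with `expression` (matrix), `cna` (integer-coded matrix),
#'   `survival` (`survival_data`), `network` (`gene_network`),
#'   `association`, `pathways`, `lit_counts` (tibbles), `censor_max` and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  censor_max <- config$censor_max %||%
    calibrate_censoring(config, config$target_censoring)
  genes <- sprintf("g%04d", seq_len(config$p))
  patients <- sprintf("p%04d", seq_len(config$n))
  withr::with_seed(config$seed, {
    # block-correlated expression: sqrt(rho) * module factor + noise
    x <- matrix(rnorm(config$n * config$p), config$n, config$p,
                dimnames = list(patients, genes))
    if (config$n_modules > 0 && config$rho_within > 0) {
      f <- matrix(rnorm(config$n * config$n_modules), config$n)
      for (m in seq_len(config$n_modules)) {
        cols <- ((m - 1) * config$module_size + 1):(m * config$module_size)
        x[, cols] <- sqrt(config$rho_within) * f[, m] +
          sqrt(1 - config$rho_within) * x[, cols]
      }
    }
    eta <- if (length(config$support) > 0) {
      drop(x[, config$support, drop = FALSE] %*% config$beta_true)
    } else {
      numeric(config$n)
    }
    t_true <- -log(runif(config$n)) / (config$baseline_hazard * exp(eta))
    cens <- runif(config$n, 0, censor_max)
    surv <- survival_data(tibble::tibble(
      patient_id = patients,
      time = pmin(t_true, cens),
      event = as.integer(t_true <= cens)))
    if (all(surv$event == 0)) warn("simulated cohort is fully censored")
    # within-module complete network
    edges <- NULL
    if (config$n_modules > 0) {
      edges <- purrr::map_dfr(seq_len(config$n_modules), function(m) {
        cols <- ((m - 1) * config$module_size + 1):(m * config$module_size)
        pairs <- utils::combn(genes[cols], 2)
        tibble::tibble(from = pairs[1, ], to = pairs[2, ],
                       weight = config$rho_within)
      })
    }
    net <- gene_network(edges %||% tibble::tibble(from = character(),
                                                  to = character(),
                                                  weight = double()))
    # partial biomedical knowledge: a subset of causal genes is "known"
    causal <- genes[config$support]
    n_known <- round(config$assoc_causal_frac * length(causal))
    known <- causal[sample_int_safe(length(causal), n_known)]
    others <- setdiff(genes, known)
    covered <- others[sample_int_safe(
      length(others), round(config$assoc_coverage * length(others)))]
    association <- dplyr::arrange(tibble::tibble(
      gene = c(known, covered),
      assoc_p = c(runif(length(known), 0, 0.049),
                  runif(length(covered), 0.05, 1))), .data$gene)
    # one pathway per module
    pathways <- if (config$n_modules > 0) {
      purrr::map_dfr(seq_len(config$n_modules), function(m) {
        cols <- ((m - 1) * config$module_size + 1):(m * config$module_size)
        tibble::tibble(gene = genes[cols], pathway = sprintf("PW%02d", m))
      })
    } else {
      tibble::tibble(gene = character(), pathway = character())
    }
    lit_counts <- tibble::tibble(
      gene = causal,
      lit_count = if (length(causal)) sample.int(50, length(causal),
                                                 replace = TRUE) else integer())
    # CNA: 5-bin threshold of a concordance-mixed copy of the z-scores
    use_x <- matrix(rbinom(config$n * config$p, 1, config$cna_concordance),
                    config$n, config$p)
    zz <- use_x * x + (1 - use_x) *
      matrix(rnorm(config$n * config$p), config$n, config$p)
    cna <- matrix(as.double(cut(zz, c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf),
                                labels = FALSE) - 3L),
                  config$n, config$p, dimnames = dimnames(x))
    list(expression = x, cna = cna, survival = surv, network = net,
         association = association, pathways = pathways,
         lit_counts = lit_counts, censor_max = censor_max, config = config)
  })
}

# sample.int that returns integer(0) for size 0 without warning
sample_int_safe <- function(n, size) {
  if (size <= 0 || n == 0) return(integer(0))
  sample.int(n, min(size, n))
}

#' Write a simulated cohort as the six canonical fixture files
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(sim$expression, file.path(dir, "expression.tsv"))
  write_table(sim$cna, file.path(dir, "cna.tsv"))
  write_table(sim$survival, file.path(dir, "survival.tsv"))
  write_table(sim$network, file.path(dir, "network.tsv"))
  write_table(sim$association, file.path(dir, "association.tsv"))
  write_table(sim$pathways, file.path(dir, "pathways.tsv"))
  invisible(dir)
}
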