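#' Run the screening-network survival-prediction pipeline end-to-end
#'
#' Orchestrates, on a training cohort: variable screening (biomedical,
#' data-driven or their union), normalized-Laplacian construction on the
#' screened set, repeated K-fold cross-validated partial-likelihood tuning
#' of lambda at fixed alpha, a final network-penalized Cox fit, adaptive
#' prognostic-index cutoff selection; then validates the fixed signature
#' and cutoff on a held-out cohort with the two-group log-rank test. With
#' a vector of data-driven screening sizes, the whole procedure repeats
#' per threshold and a consensus gene table (selection frequency across
#' thresholds) is added.
#'
#' Test-set survival outcomes are consumed exclusively by
#' [evaluate_testset()]; screening, tuning and cutoff selection see
#' training data only.
#'
#' @param train,test Lists with elements `expression` (patient x gene
#'   matrix or tibble) and `survival` (`survival_data`); training and test
#'   patient ids must be disjoint.
#' @param network A `gene_network` over the measured genes.
#' @param association Association tibble, required for modes `"bmd"` and
#'   `"union"`.
#' @param pathways Optional pathway membership tibble for the report.
#' @param lit_counts Optional literature-count tibble (known-marker flag).
#' @param mode Screening mode: `"union"` (default), `"bmd"` or `"dad"`.
#' @param method Solver for the final fit: `"adalnet"` or `"admmnet"`.
#' @param alpha Network-balance parameter (default 0.5).
#' @param alpha_cut BMD inclusion cutoff (default 0.05).
#' @param d_dad Data-driven screening size, scalar or vector of
#'   thresholds; default `floor(n log n)` capped at `p`.
#' @param cv Cross-validation settings; its seed is overridden by `seed`.
#' @param seed Integer seed for every random choice (fold shuffles).
#' @param out_dir Optional directory; when given, all artifacts and a
#'   manifest (input checksums, seed, package version) are written there.
#' @param verbose Emit one structured log line per stage (default TRUE).
#' @return An `snp_run` object: `results` (one row per threshold),
#'   `runs` (per-threshold details: screen, cv, fit, model, evaluation,
#'   pathway graph) and `consensus`.
#' @export
run_pipeline <- function(train, test, network, association = NULL,
                         pathways = NULL, lit_counts = NULL,
                         mode = c("union", "bmd", "dad"),
                         method = c("adalnet", "admmnet"),
                         alpha = 0.5, alpha_cut = 0.05, d_dad = NULL,
                         cv = cv_settings(), seed = 1, out_dir = NULL,
                         verbose = TRUE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  say <- function(...) if (verbose) message(sprintf(...))
  tr <- align_patients(train$expression, train$survival)
  te <- align_patients(test$expression, test$survival)
  overlap <- intersect(rownames(tr$x), rownames(te$x))
  if (length(overlap) > 0) {
    abort(paste0("training and test sets overlap in ", length(overlap),
                 " patient(s)"),
          class = "screennet_validation_error")
  }
  if (mode %in% c("bmd", "union") && is.null(association)) {
    abort("association table required for BMD screening",
          class = "screennet_config_error")
  }
  if (is.null(d_dad)) {
    d_dad <- min(default_dad_size(nrow(tr$x)), ncol(tr$x))
  }
  d_grid <- sort(unique(as.integer(d_dad)))
  if (any(d_grid <= 0)) abort("d_dad thresholds must be positive")
  cv$seed <- as.integer(seed)
  say("[pipeline] stage=input train=%dx%d test=%dx%d mode=%s method=%s seed=%d",
      nrow(tr$x), ncol(tr$x), nrow(te$x), ncol(te$x), mode, method, seed)

  bmd <- NULL
  if (mode %in% c("bmd", "union")) {
    bmd <- bmd_screen(association, colnames(tr$x), alpha_cut)
    say("[pipeline] stage=bmd_screen d_bmd=%d alpha_cut=%g", nrow(bmd),
        alpha_cut)
  }

  runs <- list()
  for (d in d_grid) {
    stage <- tryCatch(
      run_one_threshold(tr, te, network, bmd, mode, method, alpha, d, cv,
                        pathways, lit_counts, association, say),
      error = function(e) {
        abort(paste0("pipeline failed at d_dad=", d, ": ",
                     conditionMessage(e)), parent = e)
      })
    runs[[as.character(d)]] <- stage
  }
  results <- purrr::map_dfr(runs, "summary")
  consensus <- consensus_table(lapply(runs, function(r) r$model$genes))
  out <- structure(list(results = results, runs = runs,
                        consensus = consensus, mode = mode, method = method,
                        alpha = alpha, seed = seed),
                   class = "snp_run")
  if (!is.null(out_dir)) {
    write_run(out, train, test, network, association, out_dir)
  }
  out
}

run_one_threshold <- function(tr, te, network, bmd, mode, method, alpha,
                              d, cv, pathways, lit_counts, association,
                              say) {
  screen <- switch(mode,
    bmd = bmd,
    dad = dad_screen(tr$x, tr$surv, min(d, ncol(tr$x))),
    union = union_screen(bmd, dad_screen(tr$x, tr$surv, min(d, ncol(tr$x)))))
  if (nrow(screen) == 0) abort("screening selected no genes")
  say("[pipeline] stage=screen d_dad=%d kind=%s d=%d", d,
      attr(screen, "kind"), nrow(screen))
  x_tr <- tr$x[, screen$gene, drop = FALSE]
  x_te <- te$x[, screen$gene, drop = FALSE]

  cvres <- select_lambda(x_tr, tr$surv, network, method, cv)
  say("[pipeline] stage=tune lambda_hat=%.5g (mean %.5g over %d repeats)",
      cvres$lambda_hat, cvres$lambda_mean, cv$repeats)

  fit <- if (method == "adalnet") {
    fit_adalnet(x_tr, tr$surv, network, cvres$lambda_hat, alpha)
  } else {
    fit_admmnet(x_tr, tr$surv, network, cvres$lambda_hat, alpha)
  }
  model <- as_risk_model(fit)
  say("[pipeline] stage=fit method=%s n_signature=%d objective=%.6g",
      method, length(model$genes), fit$objective)

  evaluation <- NULL
  if (length(model$genes) > 0) {
    model <- calibrate_cutoff(model, x_tr, tr$surv)
    say("[pipeline] stage=cutoff gamma_star=%.2f pi_star=%.5g train_p=%.3g",
        model$gamma_star, model$pi_star, model$train_p)
    evaluation <- evaluate_testset(x_te, te$surv, model)
    say("[pipeline] stage=validate evaluable=%s test_p=%s",
        evaluation$evaluable,
        if (evaluation$evaluable) sprintf("%.3g", evaluation$logrank$p)
        else "NA")
  } else {
    say("[pipeline] stage=cutoff skipped: empty signature")
  }

  report <- NULL
  if (!is.null(pathways) && length(model$genes) > 0) {
    cats <- if (!is.null(association)) {
      categorize_genes(model$genes, association)
    }
    report <- comembership_graph(model$genes, pathways, cats, lit_counts)
  }
  km <- list(
    train = kaplan_meier(tr$surv),
    test_high = NULL, test_low = NULL)
  if (!is.null(evaluation) && evaluation$evaluable) {
    hi <- evaluation$groups$group == "high"
    km$test_high <- kaplan_meier(te$surv[hi, , drop = FALSE])
    km$test_low <- kaplan_meier(te$surv[!hi, , drop = FALSE])
  }
  summary <- tibble::tibble(
    d_dad = d, kind = attr(screen, "kind"), d_screened = nrow(screen),
    lambda_hat = cvres$lambda_hat, n_signature = length(model$genes),
    gamma_star = model$gamma_star, pi_star = model$pi_star,
    train_p = model$train_p %||% NA_real_,
    test_p = if (!is.null(evaluation) && evaluation$evaluable) {
      evaluation$logrank$p
    } else {
      NA_real_
    },
    evaluable = !is.null(evaluation) && evaluation$evaluable)
  list(summary = summary, screen = screen, cv = cvres, fit = fit,
       model = model, evaluation = evaluation, pathway_graph = report,
       km = km)
}

#' Consensus gene table across screening thresholds
#'
#' Counts, per gene, the number of threshold runs whose final signature
#' contains it; sorted by decreasing frequency.
#'
#' @param signatures List of character vectors (one signature per
#'   threshold).
#' @return Tibble with `gene` and `frequency`.
#' @export
consensus_table <- function(signatures) {
  stopifnot(length(signatures) >= 1)
  genes <- unlist(signatures, use.names = FALSE)
  if (length(genes) == 0) {
    return(tibble::tibble(gene = character(), frequency = integer()))
  }
  tb <- table(genes)
  tibble::tibble(gene = names(tb), frequency = as.integer(tb)) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$gene)
}

#' @export
print.snp_run <- function(x, ...) {
  cat(sprintf("<snp_run> mode=%s method=%s alpha=%g, %d threshold run(s)\n",
              x$mode, x$method, x$alpha, nrow(x$results)))
  print(x$results)
  invisible(x)
}

write_run <- function(run, train, test, network, association, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(run$results, file.path(out_dir, "results.tsv"))
  write_table(run$consensus, file.path(out_dir, "consensus.tsv"))
  for (d in names(run$runs)) {
    r <- run$runs[[d]]
    pre <- file.path(out_dir, paste0("d", d))
    sig <- tibble::tibble(gene = r$model$genes, beta = r$model$beta)
    write_table(sig, paste0(pre, "_signature.tsv"))
    write_table(tidy(r$screen), paste0(pre, "_screen.tsv"))
    if (!is.null(r$evaluation)) {
      write_table(r$evaluation$groups, paste0(pre, "_groups.tsv"))
      if (r$evaluation$evaluable) {
        jsonlite::write_json(
          list(chi2 = r$evaluation$logrank$chi2, p = r$evaluation$logrank$p),
          paste0(pre, "_logrank.json"), auto_unbox = TRUE, digits = NA)
      }
    }
    write_table(r$km$train, paste0(pre, "_km_train.tsv"))
    if (!is.null(r$pathway_graph)) {
      write_sif(r$pathway_graph, paste0(pre, "_comembership.sif"))
    }
  }
  manifest <- list(
    seed = run$seed, mode = run$mode, method = run$method,
    alpha = run$alpha,
    package_version = as.character(utils::packageVersion("screennet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    input_checksums = list(
      train_expression = object_md5(train$expression),
      train_survival = object_md5(train$survival),
      test_expression = object_md5(test$expression),
      test_survival = object_md5(test$survival),
      network = object_md5(network),
      association = object_md5(association)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# md5 of a serialized in-memory object (version-pinned serialization)
object_md5 <- function(x) {
  if (is.null(x)) return(NA_character_)
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
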