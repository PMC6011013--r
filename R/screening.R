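#' Marginal Cox maximum likelihood estimate for a single gene
#'
#' Maximizes the univariate Cox log partial likelihood (Breslow ties) for
#' one covariate. Monotone likelihoods (divergent maximizer) and constant
#' columns are reported as degenerate with `beta = 0`.
#'
#' @param x_k Numeric vector, one value per patient.
#' @param surv A `survival_data` tibble in the same patient order.
#' @param divergence_bound Flag the fit as degenerate when the maximizer
#'   exceeds this magnitude (default 15: a log hazard ratio beyond any
#'   biological plausibility on standardized expression).
#' @return List with `beta` (the MMLE, 0 when degenerate) and `degenerate`.
#' @export
marginal_cox_mmle <- function(x_k, surv, divergence_bound = 15) {
  stopifnot(length(x_k) == nrow(surv))
  if (any(!is.finite(x_k))) abort("non-finite covariate values")
  if (sum(surv$event) < 1) abort("no events", class = "screennet_validation_error")
  if (sd(x_k) == 0) return(list(beta = 0, degenerate = TRUE))
  oo <- cox_order(surv$time, surv$event)
  negll <- function(b) -cox_eta_derivs(x_k * b, oo)$logpl
  bound <- divergence_bound + 1
  opt <- optimize(negll, c(-bound, bound), tol = 1e-9)
  if (abs(opt$minimum) > divergence_bound) {
    return(list(beta = 0, degenerate = TRUE))
  }
  list(beta = opt$minimum, degenerate = FALSE)
}

# MMLE for every column of x (already aligned with surv)
marginal_mmle_all <- function(x, surv, divergence_bound = 15) {
  betas <- numeric(ncol(x))
  degen <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    r <- marginal_cox_mmle(x[, j], surv, divergence_bound)
    betas[j] <- r$beta
    degen[j] <- r$degenerate
  }
  tibble::tibble(gene = colnames(x), marginal_beta = betas, degenerate = degen)
}

new_screen_result <- function(tbl, kind, threshold_used, universe) {
  attr(tbl, "kind") <- kind
  attr(tbl, "threshold_used") <- threshold_used
  attr(tbl, "universe") <- universe
  class(tbl) <- c("screen_result", class(tbl))
  tbl
}

#' Biomedical-driven (BMD) screening
#'
#' Keeps the genes whose external disease-association p-value is at or
#' below `alpha_cut` (inclusive), restricted to genes actually measured in
#' the matrix. No multiplicity control is applied at this stage: screening
#' pre-selects features, the penalized fit does the selection.
#'
#' @param table Association tibble (columns `gene`, `assoc_p`); see
#'   [association_table()].
#' @param genes Character vector of measured genes (matrix column names).
#' @param alpha_cut Inclusion cutoff in (0, 1), default 0.05.
#' @return A `screen_result` tibble (columns `gene`, `marginal_beta`,
#'   `degenerate`, `source`) with attributes `kind = "BMD"` and
#'   `threshold_used = alpha_cut`.
#' @export
bmd_screen <- function(table, genes, alpha_cut = 0.05) {
  stopifnot(alpha_cut > 0, alpha_cut < 1)
  table <- association_table(table)
  keep <- table$gene[table$assoc_p <= alpha_cut]
  keep <- intersect(genes, keep)          # preserve matrix column order
  if (length(keep) == 0) warn("BMD screening selected no genes")
  out <- tibble::tibble(gene = keep, marginal_beta = NA_real_,
                        degenerate = NA, source = "BMD")
  new_screen_result(out, "BMD", alpha_cut, genes)
}

#' Data-driven (DAD) sure-independence screening
#'
#' Computes the marginal Cox MMLE for every gene on internally standardized
#' columns (mean 0, sd 1, so coefficient magnitudes are scale-free), ranks
#' genes by `|beta^M|` descending and keeps the top `d_dad`. Genes tied in
#' magnitude with the cutoff gene are all kept, so the result can slightly
#' exceed `d_dad`; degenerate genes rank last. The implied magnitude
#' threshold (the `|beta^M|` of the last ranked gene kept) is recorded in
#' the `threshold_used` attribute.
#'
#' @param x Patient x gene matrix (or tibble form).
#' @param surv Aligned `survival_data`.
#' @param d_dad Number of genes to keep; default `floor(n log n)` capped at
#'   `p` (see [default_dad_size()]).
#' @return A `screen_result` tibble, genes in rank order.
#' @export
dad_screen <- function(x, surv, d_dad = NULL) {
  x <- as_omics_matrix(x)
  check_paired(x, surv)
  d_dad <- d_dad %||% min(default_dad_size(nrow(x)), ncol(x))
  if (d_dad <= 0) abort("d_dad must be positive")
  if (d_dad > ncol(x)) abort("d_dad exceeds the number of genes")
  xs <- standardize_columns(x)$x
  mm <- marginal_mmle_all(xs, surv)
  score <- abs(mm$marginal_beta)
  score[mm$degenerate] <- -Inf            # degenerate genes rank last
  ord <- order(score, decreasing = TRUE)
  cut_score <- score[ord][d_dad]
  keep <- if (is.finite(cut_score)) {
    which(score >= cut_score)             # include all ties at the cutoff
  } else {
    ord[seq_len(d_dad)]
  }
  keep <- ord[ord %in% keep]
  out <- tibble::tibble(gene = mm$gene[keep],
                        marginal_beta = mm$marginal_beta[keep],
                        degenerate = mm$degenerate[keep],
                        source = "DAD")
  new_screen_result(out, "DAD",
                    threshold_used = if (is.finite(cut_score)) cut_score else 0,
                    universe = colnames(x))
}

#' Default data-driven screening size
#'
#' The customary sure-independence screening size `floor(n log n)` (natural
#' logarithm) for a cohort of `n` patients.
#'
#' @param n Number of patients, at least 2.
#' @return A positive integer.
#' @examples
#' default_dad_size(100)  # 460
#' @export
default_dad_size <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    abort("n must be a single integer >= 2")
  }
  as.integer(floor(n * log(n)))
}

#' Union (BMD+DAD) screening
#'
#' Merges a biomedical-driven and a data-driven screen by set union;
#' marginal statistics are carried over where available. Commutative and
#' idempotent in the selected gene set.
#'
#' @param a,b Two `screen_result` objects over the same gene universe.
#' @return A `screen_result` with `kind = "BMD+DAD"`.
#' @export
union_screen <- function(a, b) {
  stopifnot(inherits(a, "screen_result"), inherits(b, "screen_result"))
  if (!setequal(attr(a, "universe"), attr(b, "universe"))) {
    abort("screen results refer to different gene universes",
          class = "screennet_validation_error")
  }
  all_genes <- union(a$gene, b$gene)
  pick <- function(res, col) {
    setNames(res[[col]], res$gene)
  }
  mb <- rep(NA_real_, length(all_genes)); names(mb) <- all_genes
  dg <- rep(NA, length(all_genes)); names(dg) <- all_genes
  src <- character(length(all_genes)); names(src) <- all_genes
  for (res in list(a, b)) {
    has_beta <- res$gene[!is.na(res$marginal_beta)]
    mb[has_beta] <- pick(res, "marginal_beta")[has_beta]
    dg[has_beta] <- pick(res, "degenerate")[has_beta]
  }
  src[all_genes %in% a$gene & all_genes %in% b$gene] <- "BMD+DAD"
  src[all_genes %in% a$gene & !all_genes %in% b$gene] <- attr(a, "kind")
  src[!all_genes %in% a$gene & all_genes %in% b$gene] <- attr(b, "kind")
  out <- tibble::tibble(gene = all_genes, marginal_beta = unname(mb),
                        degenerate = unname(dg), source = unname(src))
  new_screen_result(out, "BMD+DAD",
                    threshold_used = NA_real_,
                    universe = attr(a, "universe"))
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> kind=%s, %d gene(s) selected\n",
              attr(x, "kind"), nrow(x)))
  NextMethod()
}

# center and scale columns; constant columns get sd 1 (stay zero)
standardize_columns <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}
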