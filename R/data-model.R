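#' Construct and validate a survival table
#'
#' A survival table records, per patient, the observed follow-up time
#' `t_i = min(T_i, C_i)` in months and the event indicator
#' `delta_i = I(T_i <= C_i)` (1 = died of disease, 0 = censored).
#'
#' @param data A data frame with one row per patient.
#' @param patient_id,time,event Column names (strings) holding the patient
#'   identifier, the positive follow-up time, and the 0/1 event indicator.
#' @return A tibble with columns `patient_id` (character), `time` (double)
#'   and `event` (integer in \{0, 1\}), classed `survival_data`.
#' @examples
#' survival_data(data.frame(patient_id = c("a", "b", "c"),
#'                          time = c(1, 2, 3), event = c(1, 0, 1)))
#' @export
survival_data <- function(data, patient_id = "patient_id",
                          time = "time", event = "event") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(patient_id, time, event), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("survival table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "screennet_config_error")
  }
  out <- tibble::tibble(
    patient_id = as.character(data[[patient_id]]),
    time       = as.double(data[[time]]),
    event      = as.integer(data[[event]])
  )
  bad_time <- which(!is.finite(out$time) | out$time <= 0)
  if (length(bad_time) > 0) {
    abort(paste0("follow-up times must be positive and finite; offending row(s): ",
                 paste(head(bad_time, 5), collapse = ", ")),
          class = "screennet_validation_error")
  }
  bad_event <- which(!(data[[event]] %in% c(0, 1)))
  if (length(bad_event) > 0) {
    abort(paste0("event indicator must be 0 or 1; offending row(s): ",
                 paste(head(bad_event, 5), collapse = ", ")),
          class = "screennet_validation_error")
  }
  if (anyDuplicated(out$patient_id)) {
    abort("patient ids must be unique", class = "screennet_validation_error")
  }
  class(out) <- c("survival_data", class(out))
  out
}

#' Coerce to the internal expression-matrix representation
#'
#' User-facing functions accept either a base numeric matrix (rownames =
#' patient ids, colnames = gene symbols) or a data frame whose first column
#' is the patient id and whose remaining columns are one gene each. This
#' helper normalises both to the matrix form used internally.
#'
#' @param x Matrix or data frame as described above.
#' @param integer_coded When `TRUE`, entries are validated as copy-number
#'   codes in \{-2, -1, 0, 1, 2\} (homozygous deletion through high-level
#'   amplification).
#' @return A numeric matrix with patient rownames and gene colnames.
#' @export
as_omics_matrix <- function(x, integer_coded = FALSE) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
  } else {
    abort("expected a matrix or a data frame with a patient-id first column")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("matrix must carry patient rownames and gene colnames")
  }
  if (anyDuplicated(colnames(m))) {
    abort("duplicate gene columns", class = "screennet_validation_error")
  }
  if (anyDuplicated(rownames(m))) {
    abort("duplicate patient ids", class = "screennet_validation_error")
  }
  if (any(!is.finite(m))) {
    abort("matrix contains non-finite entries",
          class = "screennet_validation_error")
  }
  if (integer_coded && !all(m %in% c(-2, -1, 0, 1, 2))) {
    abort("integer-coded (CNA) matrix has entries outside {-2,...,2}",
          class = "screennet_validation_error")
  }
  m
}

#' Convert an expression matrix to tibble form
#'
#' @param m Numeric matrix with patient rownames and gene colnames.
#' @return A tibble whose first column is `patient_id`.
#' @export
omics_as_tibble <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(patient_id = rownames(m)),
    tibble::as_tibble(m)
  ))
}

#' Construct a weighted undirected gene network from an edge table
#'
#' Edges are unordered gene pairs with relationship strengths in `[0, 1]`
#' (0 = no relationship, 1 = strong relationship). Self-loops are dropped
#' with a warning; duplicate pairs (in either orientation) are collapsed by
#' keeping the maximum weight.
#'
#' @param edges Data frame with columns `from`, `to`, `weight` (first three
#'   columns are used positionally if names differ).
#' @return A tibble of canonical edges (`from < to` lexicographically)
#'   classed `gene_network`.
#' @export
gene_network <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (ncol(edges) < 3) abort("edge table needs (geneA, geneB, weight) columns")
  e <- tibble::tibble(
    from   = as.character(edges[[1]]),
    to     = as.character(edges[[2]]),
    weight = as.double(edges[[3]])
  )
  if (any(!is.finite(e$weight) | e$weight < 0 | e$weight > 1)) {
    abort("edge weights must lie in [0, 1]",
          class = "screennet_validation_error")
  }
  loops <- e$from == e$to
  if (any(loops)) {
    warn(paste0("dropping ", sum(loops), " self-loop edge(s)"))
    e <- e[!loops, , drop = FALSE]
  }
  # canonical orientation, then max-collapse duplicates
  flip <- e$from > e$to
  tmp <- e$from[flip]; e$from[flip] <- e$to[flip]; e$to[flip] <- tmp
  if (nrow(e) > 0) {
    e <- e |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
      dplyr::arrange(.data$from, .data$to)
  }
  class(e) <- c("gene_network", class(e))
  e
}

#' Weighted degree of every vertex in a gene network
#'
#' @param net A `gene_network` edge tibble.
#' @param genes Optional vector of gene symbols; genes absent from the
#'   network get degree 0 (zero-weight completion).
#' @return Named numeric vector of degrees `d_i = sum_j w_ij`.
#' @export
network_degrees <- function(net, genes = NULL) {
  all_genes <- genes %||% sort(unique(c(net$from, net$to)))
  d <- setNames(numeric(length(all_genes)), all_genes)
  keep <- net$from %in% all_genes & net$to %in% all_genes
  e <- net[keep, , drop = FALSE]
  if (nrow(e) > 0) {
    t1 <- tapply(e$weight, e$from, sum)
    t2 <- tapply(e$weight, e$to, sum)
    d[names(t1)] <- d[names(t1)] + t1
    d[names(t2)] <- d[names(t2)] + t2
  }
  d
}

#' Validate a gene-disease association table
#'
#' External biomedical evidence in the form of one association p-value per
#' gene, used by biomedical-driven screening and by signature categorisation.
#'
#' @param data Data frame with columns `gene` and `assoc_p`.
#' @return Tibble with unique genes and `assoc_p` in `[0, 1]`.
#' @export
association_table <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("gene", "assoc_p") %in% names(data))) {
    abort("association table needs columns gene, assoc_p",
          class = "screennet_config_error")
  }
  out <- tibble::tibble(gene = as.character(data$gene),
                        assoc_p = as.double(data$assoc_p))
  if (any(!is.finite(out$assoc_p) | out$assoc_p < 0 | out$assoc_p > 1)) {
    abort("association p-values must lie in [0, 1]",
          class = "screennet_validation_error")
  }
  if (anyDuplicated(out$gene)) {
    abort("association table genes must be unique",
          class = "screennet_validation_error")
  }
  out
}

#' Align an expression matrix with a survival table
#'
#' Patients present in only one of the two inputs are dropped with a
#' warning; the returned pair shares one patient order. Mismatched inputs
#' never proceed silently into a fit.
#'
#' @param x Expression matrix (or tibble, see [as_omics_matrix()]).
#' @param surv A `survival_data` tibble.
#' @return List with elements `x` (matrix) and `surv`, row-aligned.
#' @export
align_patients <- function(x, surv) {
  m <- as_omics_matrix(x)
  common <- intersect(surv$patient_id, rownames(m))
  if (length(common) == 0) {
    abort("no patients shared between matrix and survival table",
          class = "screennet_validation_error")
  }
  n_drop <- (nrow(m) - length(common)) + (nrow(surv) - length(common))
  if (n_drop > 0) {
    warn(paste0("dropping ", n_drop,
                " patient record(s) absent from the other input"))
  }
  surv2 <- surv[match(common, surv$patient_id), , drop = FALSE]
  list(x = m[common, , drop = FALSE], surv = surv2)
}
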