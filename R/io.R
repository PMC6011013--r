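#' Read a survival table from delimited text
#'
#' @param path Path to a TSV (default) or CSV file with a header row.
#' @param patient_id,time,event Names of the mapped columns.
#' @param status_levels When `event` maps to a 3-level status column, a named
#'   character vector giving the labels for died-of-disease, living and
#'   died-of-other-causes; the latter two are censored (event = 0).
#' @param delim Field delimiter; `"\t"` (canonical) or `","`.
#' @return A `survival_data` tibble.
#' @export
read_survival <- function(path, patient_id = "patient_id", time = "time",
                          event = "event", status_levels = NULL,
                          delim = "\t") {
  df <- read_delim_strict(path, delim)
  if (!is.null(status_levels)) {
    stopifnot(all(c("died_of_disease", "living", "died_other") %in%
                    names(status_levels)))
    if (!event %in% names(df)) {
      abort(paste0("survival table is missing column(s): ", event),
            class = "screennet_config_error")
    }
    status <- as.character(df[[event]])
    unknown <- setdiff(unique(status), unname(status_levels))
    if (length(unknown) > 0) {
      abort(paste0("unknown status label(s): ", paste(unknown, collapse = ", ")),
            class = "screennet_validation_error")
    }
    df[[event]] <- as.integer(status == status_levels[["died_of_disease"]])
  }
  survival_data(df, patient_id = patient_id, time = time, event = event)
}

#' Read a patient x gene matrix from delimited text
#'
#' First column = patient id, header row = gene symbols.
#'
#' @inheritParams read_survival
#' @param integer_coded Validate entries as CNA codes in \{-2,...,2\}.
#' @return Numeric matrix with patient rownames and gene colnames.
#' @export
read_matrix <- function(path, integer_coded = FALSE, delim = "\t") {
  df <- read_delim_strict(path, delim)
  as_omics_matrix(df, integer_coded = integer_coded)
}

#' Read a weighted edge list
#'
#' Rows are `(geneA, geneB, weight)` with weights in `[0, 1]`.
#'
#' @inheritParams read_survival
#' @return A `gene_network` tibble.
#' @export
read_edge_list <- function(path, delim = "\t") {
  gene_network(read_delim_strict(path, delim))
}

#' Read a gene-disease association table
#'
#' @inheritParams read_survival
#' @return Validated association tibble (columns `gene`, `assoc_p`).
#' @export
read_association_table <- function(path, delim = "\t") {
  association_table(read_delim_strict(path, delim))
}

#' Read a gene-to-pathway membership table
#'
#' Long format: one row per (gene, pathway) pair.
#'
#' @inheritParams read_survival
#' @return Tibble with columns `gene`, `pathway`.
#' @export
read_pathways <- function(path, delim = "\t") {
  df <- read_delim_strict(path, delim)
  if (!all(c("gene", "pathway") %in% names(df))) {
    abort("pathway table needs columns gene, pathway",
          class = "screennet_config_error")
  }
  tibble::tibble(gene = as.character(df$gene),
                 pathway = as.character(df$pathway))
}

# base-R parser: strtod is correctly rounded, so %.17g output from the
# writers round-trips bit-exactly
read_delim_strict <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "screennet_config_error")
  }
  df <- utils::read.delim(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    abort(paste0("no data rows in ", path),
          class = "screennet_validation_error")
  }
  tibble::as_tibble(df)
}

#' Write tabular containers in the dialect the readers consume
#'
#' @param x A data frame, `survival_data`, `gene_network`, or a matrix with
#'   patient rownames (written with a leading `patient_id` column).
#' @param path Output path.
#' @param delim Field delimiter (`"\t"` canonical).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = "\t") {
  if (is.matrix(x)) x <- omics_as_tibble(x)
  df <- as.data.frame(x)
  # %.17g round-trips every double bit-exactly through the reader
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  readr::write_delim(df, path, delim = delim, progress = FALSE)
  invisible(path)
}
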