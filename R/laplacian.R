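#' Induced subnetwork on a gene set, with zero-weight completion
#'
#' Restricts a weighted gene network to the given genes. Genes not covered
#' by the network simply become isolated vertices (degree 0); their
#' Laplacian rows are zero, so downstream they incur only the sparsity
#' penalty.
#'
#' @param net A `gene_network` edge tibble.
#' @param genes Ordered character vector of gene symbols (typically a
#'   screened set).
#' @return A `gene_network` restricted to edges with both endpoints in
#'   `genes`, with attribute `vertices` carrying the full ordered gene set.
#' @export
subnetwork <- function(net, genes) {
  keep <- net$from %in% genes & net$to %in% genes
  e <- net[keep, , drop = FALSE]
  attr(e, "vertices") <- genes
  class(e) <- unique(c("gene_network", class(e)))
  e
}

#' Normalized Laplacian of a gene network on an ordered gene set
#'
#' Builds the degree vector `d_i = sum_j w_ij` and the normalized Laplacian
#' `L` with `L_ii = 1` when `d_i != 0` (0 otherwise) and
#' `L_ij = -w_ij / sqrt(d_i d_j)` on edges. `L` is symmetric positive
#' semi-definite with eigenvalues in `[0, 2]`; isolated genes contribute
#' all-zero rows.
#'
#' @param net A `gene_network` edge tibble.
#' @param genes Ordered, unique gene symbols defining the row/column order
#'   (fixed to the screening order downstream).
#' @return List with `genes`, `degrees` (named vector) and `L` (dense
#'   symmetric matrix), classed `laplacian_bundle`.
#' @export
normalized_laplacian <- function(net, genes) {
  stopifnot(!anyDuplicated(genes))
  d <- network_degrees(net, genes)
  p <- length(genes)
  L <- matrix(0, p, p, dimnames = list(genes, genes))
  if (p > 0) diag(L) <- as.numeric(d > 0)
  e <- subnetwork(net, genes)
  if (nrow(e) > 0) {
    i <- match(e$from, genes)
    j <- match(e$to, genes)
    v <- -e$weight / sqrt(d[i] * d[j])
    L[cbind(i, j)] <- L[cbind(i, j)] + v
    L[cbind(j, i)] <- L[cbind(j, i)] + v
  }
  structure(list(genes = genes, degrees = d, L = L),
            class = "laplacian_bundle")
}

#' @export
print.laplacian_bundle <- function(x, ...) {
  cat(sprintf("<laplacian_bundle> %d gene(s), %d connected\n",
              length(x$genes), sum(x$degrees > 0)))
  invisible(x)
}
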