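#' Collapse probe-level expression to gene level
#'
#' Probes mapping to no gene (empty/NA entry in the map) are removed; when
#' several probes map to the same gene, the per-sample median across those
#' probes is used as the gene's expression value (even probe counts take the
#' mean of the two central order statistics, the conventional median).
#'
#' @param probe_matrix Numeric matrix, probes x samples, with probe ids as
#'   row names.
#' @param probe_map Data frame with columns `probe_id` and `gene_id`; an
#'   empty string or NA `gene_id` marks an unmapped probe. Every probe in
#'   the matrix must appear in the map.
#' @return Numeric matrix, genes x samples; genes ordered by first
#'   occurrence among the mapped probes.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  stopifnot(is.matrix(probe_matrix), !is.null(rownames(probe_matrix)))
  if (!all(c("probe_id", "gene_id") %in% names(probe_map)))
    stop("'probe_map' needs columns probe_id and gene_id")
  if (anyDuplicated(probe_map$probe_id)) stop("duplicate probe ids in map")
  idx <- match(rownames(probe_matrix), probe_map$probe_id)
  if (anyNA(idx))
    stop("probe(s) absent from the probe map: ",
         paste(rownames(probe_matrix)[is.na(idx)], collapse = ", "))
  gene <- as.character(probe_map$gene_id)[idx]
  mapped <- !is.na(gene) & nzchar(gene)   # "the empty probe" is dropped
  m <- probe_matrix[mapped, , drop = FALSE]
  gene <- gene[mapped]
  if (nrow(m) == 0L) stop("no mapped probes left after removal")
  gene <- factor(gene, levels = unique(gene))
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), gene), function(ix) {
    if (length(ix) == 1L) m[ix, ] else apply(m[ix, , drop = FALSE], 2, stats::median)
  }))
  rownames(out) <- levels(gene)
  colnames(out) <- colnames(probe_matrix)
  out
}

#' Remove additive and multiplicative batch effects
#'
#' Parametric empirical-Bayes location/scale batch adjustment (ComBat, via
#' the sva package): per gene and batch, additive and multiplicative batch
#' effects are estimated, shrunk toward common priors across genes, and
#' removed. No biological covariates are preserved; the design assumes
#' biology is batch-balanced. Matrix shape and row/column order are
#' unchanged.
#'
#' @param matrix Numeric genes x samples matrix (log scale).
#' @param batch Per-sample batch labels (vector of length `ncol(matrix)`).
#' @return Adjusted matrix of identical dimensions. With a single batch the
#'   input is returned unchanged, with a warning.
#' @export
batch_adjust <- function(matrix, batch) {
  stopifnot(is.matrix(matrix), length(batch) == ncol(matrix))
  if (any(!is.finite(matrix))) stop("expression values must be finite")
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) {
    warning("single batch: returning input unchanged")
    return(matrix)
  }
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("batch(es) with a single sample (variance inestimable): ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  out <- suppressMessages(
    sva::ComBat(dat = matrix, batch = batch, par.prior = TRUE,
                prior.plots = FALSE))
  dimnames(out) <- dimnames(matrix)
  out
}
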