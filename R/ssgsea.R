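#' Single-sample gene set enrichment scores (ssGSEA)
#'
#' For each sample, genes are ranked by expression (ascending, average ranks
#' for ties) and walked in order of decreasing rank (ties in rank broken by
#' lexicographic gene id, for reproducibility on discrete data). The
#' enrichment score of set S is the integrated difference between the
#' rank-weighted in-set cumulative distribution and the unweighted
#' out-of-set cumulative distribution:
#' \deqn{ES(S) = \sum_{i=1}^{N} \left[ P_{in}(i) - P_{out}(i) \right]}
#' with \eqn{P_{in}(i) = \sum_{g \in S, pos(g) \le i} r_g^\alpha /
#' \sum_{g \in S} r_g^\alpha} and \eqn{P_{out}(i) = |\{g \notin S,
#' pos(g) \le i\}| / (N - |S|)}, where r_g is the absolute rank (1..N).
#' With `normalize = TRUE` the whole score matrix is divided by its
#' (max - min), the GSVA-style "ssgsea.norm" convention.
#'
#' @param matrix Numeric genes x samples matrix (log scale) with gene ids as
#'   row names.
#' @param sets A [gene_set_collection()]; sets are intersected with the
#'   matrix genes and every set must remain non-empty and strictly smaller
#'   than the gene universe.
#' @param alpha Rank-weighting exponent, >= 0. Default 0.25, the ssGSEA
#'   convention. `alpha = 0` gives uniform in-set weights (a difference of
#'   empirical CDFs).
#' @param normalize Divide the score matrix by its global (max - min)?
#'   Default TRUE.
#' @return Cell types x samples numeric matrix of enrichment scores with
#'   attributes `alpha` and `normalized`.
#' @export
ssgsea_score <- function(matrix, sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            inherits(sets, "gene_set_collection"), alpha >= 0)
  if (any(!is.finite(matrix))) stop("expression values must be finite")
  ids <- rownames(matrix)
  N <- nrow(matrix)
  M <- vapply(sets$genes, function(g) ids %in% g, logical(N))
  M <- base::matrix(M, nrow = N,
                    dimnames = list(ids, names(sets$genes)))
  sizes <- colSums(M)
  if (any(sizes == 0L))
    stop("set(s) with no genes in the matrix: ",
         paste(colnames(M)[sizes == 0L], collapse = ", "))
  if (any(sizes == N))
    stop("set(s) covering every gene in the matrix (out-of-set CDF ",
         "undefined): ", paste(colnames(M)[sizes == N], collapse = ", "))
  # summing the running difference over all N positions reduces to a
  # per-gene form: each gene contributes to every position at or after its
  # own, so sum_i P_in(i) = sum_{g in S} w_g (N - pos_g + 1) / W and
  # sum_i P_out(i) = sum_{g notin S} (N - pos_g + 1) / (N - s); three
  # matrix products then score all sets and samples at once
  ns <- ncol(matrix)
  W <- base::matrix(NA_real_, N, ns)   # rank^alpha weight per gene
  U <- base::matrix(NA_real_, N, ns)   # N - position + 1 per gene
  lex <- ids  # tie-break key
  for (j in seq_len(ns)) {
    x <- matrix[, j]
    if (diff(range(x)) == 0)
      stop("constant expression in sample ", colnames(matrix)[j],
           ": ranks undefined")
    r <- rank(x)                       # ascending, average ties
    ord <- order(-r, lex)              # positions 1..N by descending rank
    pos <- integer(N); pos[ord] <- seq_len(N)
    W[, j] <- r^alpha
    U[, j] <- N - pos + 1
  }
  in_uw <- crossprod(M, U * W)
  in_w <- crossprod(M, W)
  in_u <- crossprod(M, U)
  ES <- in_uw / in_w - (N * (N + 1) / 2 - in_u) / (N - sizes)
  dimnames(ES) <- list(colnames(M), colnames(matrix))
  if (normalize) {
    rng <- max(ES) - min(ES)
    if (rng > 0) ES <- ES / rng
  }
  attr(ES, "alpha") <- alpha
  attr(ES, "normalized") <- normalize
  ES
}

#' Pairwise cell-type correlation network
#'
#' Pearson correlation between all unordered pairs of cell-type enrichment
#' profiles, with two-sided p-values from the t transform on n - 2 degrees
#' of freedom; pairs below the significance threshold are retained as
#' network edges.
#'
#' @param enrich Cell types x samples enrichment matrix.
#' @param p_threshold Retention threshold on the correlation p-value
#'   (default 1e-4).
#' @return Data frame of retained edges (`cell_a`, `cell_b`, `r`,
#'   `p_value`), with the full pair table in attribute `"all_pairs"`.
#'   Constant cell rows are excluded with a warning.
#' @export
cell_correlations <- function(enrich, p_threshold = 1e-4) {
  stopifnot(is.matrix(enrich))
  if (ncol(enrich) < 3L) stop("need at least 3 samples")
  const <- apply(enrich, 1, function(z) diff(range(z)) == 0)
  if (any(const)) {
    warning("constant cell profile(s) excluded: ",
            paste(rownames(enrich)[const], collapse = ", "))
    enrich <- enrich[!const, , drop = FALSE]
  }
  cells <- rownames(enrich)
  if (length(cells) < 2L) stop("fewer than 2 non-constant cell profiles")
  pairs <- utils::combn(length(cells), 2)
  n <- ncol(enrich)
  res <- apply(pairs, 2, function(ij) {
    r <- stats::cor(enrich[ij[1], ], enrich[ij[2], ])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
  })
  all_pairs <- data.frame(cell_a = cells[pairs[1, ]],
                          cell_b = cells[pairs[2, ]],
                          r = res["r", ], p_value = res["p", ],
                          stringsAsFactors = FALSE)
  edges <- all_pairs[all_pairs$p_value < p_threshold, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "all_pairs") <- all_pairs
  attr(edges, "p_threshold") <- p_threshold
  edges
}

#' Cluster cell types by enrichment profile
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage)
#' of row-standardized cell profiles, cut at `k` clusters. Deterministic.
#'
#' @param enrich Cell types x samples enrichment matrix.
#' @param k Number of clusters (default 4).
#' @return Named integer vector of cluster labels, one per cell type.
#' @export
cluster_cells <- function(enrich, k = 4L) {
  stopifnot(is.matrix(enrich))
  k <- as.integer(k)
  if (k < 1L || k > nrow(enrich))
    stop("k must be between 1 and the number of cell types (", nrow(enrich), ")")
  z <- t(scale(t(enrich)))
  z[!is.finite(z)] <- 0   # constant profiles standardize to 0
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  stats::cutree(hc, k = k)
}
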