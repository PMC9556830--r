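#' ESTIMATE-style stromal, immune and purity scores
#'
#' Single-sample enrichment (alpha = 0.25, unnormalized) of a stromal and
#' an immune gene signature; the ESTIMATE score is their sum and tumor
#' purity follows the published cosine transform
#' `purity = cos(0.6049872018 + 0.0001467884 * estimate_score)`. The
#' transform's constants were calibrated on Affymetrix-scale scores; if the
#' raw cosine falls outside \[0, 1\] a warning is emitted and the reported
#' purity is clipped to \[0, 1\] (the raw value is kept in `purity_raw`).
#'
#' @param matrix Genes x samples log-expression matrix.
#' @param stromal_set,immune_set Character vectors of signature genes (or
#'   single-set [gene_set_collection()]s).
#' @return Data frame: `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`, `tumor_purity`, `purity_raw`.
#' @export
estimate_scores <- function(matrix, stromal_set, immune_set) {
  as_genes <- function(s, what) {
    if (inherits(s, "gene_set_collection")) s <- unlist(s$genes, use.names = FALSE)
    s <- unique(as.character(s))
    if (length(s) == 0L) stop("empty ", what, " signature")
    s
  }
  sets <- gene_set_collection(list(
    stromal = as_genes(stromal_set, "stromal"),
    immune = as_genes(immune_set, "immune")))
  sets <- restrict_to_matrix(sets, rownames(matrix), min_size = 1L)
  if (length(sets) < 2L) stop("a signature has no genes in the matrix")
  es <- ssgsea_score(matrix, sets, alpha = 0.25, normalize = FALSE)
  estimate <- es["stromal", ] + es["immune", ]
  purity_raw <- cos(0.6049872018 + 0.0001467884 * estimate)
  if (any(purity_raw < 0 | purity_raw > 1))
    warning("purity transform outside [0, 1] for some samples; the cosine ",
            "constants are calibrated for Affymetrix-scale scores - ",
            "reported tumor_purity is clipped")
  data.frame(sample_id = colnames(matrix),
             stromal_score = unname(es["stromal", ]),
             immune_score = unname(es["immune", ]),
             estimate_score = unname(estimate),
             tumor_purity = pmin(pmax(unname(purity_raw), 0), 1),
             purity_raw = unname(purity_raw),
             stringsAsFactors = FALSE)
}

#' Moderated-t differential expression between score groups
#'
#' Per-gene two-group linear model with empirical-Bayes variance shrinkage
#' (limma): residual variances are squeezed toward a common prior and the
#' moderated t gains the prior degrees of freedom. `logFC` is the
#' high-group mean minus the low-group mean on the log scale. A gene is
#' flagged significant when `|logFC| > lfc_threshold` and the raw p-value
#' is below `p_threshold`; Benjamini-Hochberg adjusted p-values are
#' reported alongside but never filter.
#'
#' @param matrix Genes x samples log-expression matrix.
#' @param groups Per-sample labels with values `high`/`low` (factor or
#'   character), aligned with the matrix columns.
#' @param lfc_threshold Absolute log-fold-change threshold; default 0.5.
#' @param p_threshold Raw p-value threshold; default 0.05.
#' @return Data frame: `gene`, `logFC`, `t`, `p_value`, `bh_adjusted_p`,
#'   `significant`. Genes with zero variance in both groups are excluded
#'   with a warning.
#' @export
moderated_t_deg <- function(matrix, groups, lfc_threshold = 0.5,
                            p_threshold = 0.05) {
  stopifnot(is.matrix(matrix), length(groups) == ncol(matrix))
  g <- factor(as.character(groups), levels = c("low", "high"))
  if (anyNA(g)) stop("groups must be 'high'/'low'")
  if (any(table(g) < 2L)) stop("need at least 2 samples per group")
  resid_ss <- rowSums((matrix[, g == "low", drop = FALSE] -
                         rowMeans(matrix[, g == "low", drop = FALSE]))^2) +
    rowSums((matrix[, g == "high", drop = FALSE] -
               rowMeans(matrix[, g == "high", drop = FALSE]))^2)
  zero <- resid_ss == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero variance in both groups ",
            "excluded: t undefined")
    matrix <- matrix[!zero, , drop = FALSE]
  }
  design <- stats::model.matrix(~g)
  fit <- limma::eBayes(limma::lmFit(matrix, design))
  tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  data.frame(gene = rownames(matrix), logFC = tab$logFC, t = tab$t,
             p_value = tab$P.Value, bh_adjusted_p = tab$adj.P.Val,
             significant = abs(tab$logFC) > lfc_threshold &
               tab$P.Value < p_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Preranked permutation gene-set enrichment
#'
#' Classic weighted Kolmogorov-Smirnov-like running sum over the gene list
#' ranked by a per-gene statistic (descending; ties broken by gene id for
#' determinism). In-set steps are weighted by `|stat|`, out-of-set steps
#' are uniform; the enrichment score is the maximum deviation of the
#' running sum. The null is formed by `n_perm` random gene-label draws of
#' the same set size; NES divides the ES by the mean |null ES| of the same
#' sign, and the two-sided p-value is `(1 + #{|null| >= |ES|}) /
#' (n_perm + 1)`. Deterministic given `seed`.
#'
#' @param gene_stat Named numeric vector, one statistic per gene (e.g. a
#'   moderated t).
#' @param sets A [gene_set_collection()]; restricted to the ranked genes
#'   (min_size 1). A set covering every ranked gene is an error.
#' @param n_perm Number of permutations, >= 100. Default 1000.
#' @param seed Integer seed for the permutation null.
#' @return Data frame: `set`, `size`, `ES`, `NES`, `p_value`.
#' @export
ranked_enrichment <- function(gene_stat, sets, n_perm = 1000L, seed = 1L) {
  stopifnot(is.numeric(gene_stat), !is.null(names(gene_stat)),
            inherits(sets, "gene_set_collection"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  sets <- restrict_to_matrix(sets, names(gene_stat), min_size = 1L)
  N <- length(gene_stat)
  ord <- order(-gene_stat, names(gene_stat))
  stat <- gene_stat[ord]
  w <- abs(stat)
  es_of <- function(pos) {   # pos: integer positions of the set in 1..N
    inset <- logical(N); inset[pos] <- TRUE
    win <- w * inset
    tot <- sum(win)
    run <- if (tot > 0) cumsum(win) / tot
           else cumsum(inset) / sum(inset)   # all-zero stats: uniform steps
    run <- run - cumsum(!inset) / (N - length(pos))
    run[which.max(abs(run))]
  }
  set.seed(seed)
  res <- lapply(seq_along(sets$genes), function(i) {
    genes <- sets$genes[[i]]
    s <- length(genes)
    if (s >= N)
      stop("set '", names(sets$genes)[i], "' covers all ranked genes")
    es <- es_of(which(names(stat) %in% genes))
    null_es <- vapply(seq_len(n_perm),
                      function(b) es_of(sample.int(N, s)), numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    data.frame(set = names(sets$genes)[i], size = s, ES = es, NES = nes,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Wilcoxon rank-sum comparison between score groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of a per-sample feature
#' between the high and low groups: exact enumeration when the combined
#' sample size is at most 12 and there are no ties, otherwise the
#' tie-corrected normal approximation (with continuity correction).
#'
#' @param values Per-sample numeric feature.
#' @param groups Per-sample labels with exactly two levels (e.g.
#'   `high`/`low`).
#' @return List with `statistic` (rank-sum W for the first level) and
#'   `p_value`.
#' @export
group_compare <- function(values, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) == 0L)) stop("empty group")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  n <- length(x) + length(y)
  if (n < 4L) stop("need a combined sample size of at least 4")
  exact <- n <= 12L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
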