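with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full infiltration-score analysis on one cohort
#'
#' Chains every stage on an expression matrix + survival table + signature
#' collection: optional batch adjustment, ssGSEA enrichment, cell-cell
#' correlation network and cell clustering, univariate Cox screening,
#' composite-score weights, per-sample scores and median stratification,
#' Kaplan-Meier curves, log-rank test, time-dependent AUC of the composite
#' score versus each selected cell type, moderated-t differential
#' expression between groups, and (when the signatures are supplied)
#' ESTIMATE-style microenvironment scores with group comparisons and
#' preranked enrichment of the DEG statistic. Samples are reconciled by
#' inner join between the expression columns and the survival table;
#' dropped counts are reported via `message()`, never silently.
#'
#' @param expression Genes x samples log-expression matrix.
#' @param surv Survival data frame (`sample_id`, `time_months`, `event`).
#' @param signatures A [gene_set_collection()] of cell-type signatures.
#' @param batch Optional per-sample batch labels (triggers
#'   [batch_adjust()]).
#' @param out_dir Optional output directory; when given, every stage table
#'   is written as TSV and an md5 checksum manifest is returned.
#' @param alpha,normalize ssGSEA parameters (see [ssgsea_score()]).
#' @param min_set_size Signature floor passed to [restrict_to_matrix()].
#' @param p_threshold Cox screening threshold (default 0.05).
#' @param corr_p_threshold Cell-correlation edge threshold (default 1e-4).
#' @param k_clusters Number of cell clusters (default 4).
#' @param ties Median tie convention (see [assign_groups()]).
#' @param horizons AUC / survival-prediction horizons in months; default
#'   `c(72, 96, 120)`.
#' @param lfc_threshold,deg_p_threshold DEG thresholds (defaults 0.5, 0.05).
#' @param stromal_set,immune_set Optional ESTIMATE signatures (character
#'   vectors of gene ids).
#' @param enrichment_sets Optional [gene_set_collection()] for preranked
#'   enrichment of the DEG t-statistic.
#' @param n_perm Permutations for preranked enrichment.
#' @param seed Seed for the stochastic stages (currently the permutation
#'   null).
#' @return List of stage results: `samples_used`, `enrichment`, `network`,
#'   `clusters`, `screen`, `weights`, `scores`, `km`, `logrank`, `auc`,
#'   `deg`, and optionally `estimate`, `estimate_comparisons`,
#'   `enrichment_sets_result`, plus `manifest` when `out_dir` is given.
#' @export
run_pipeline <- function(expression, surv, signatures, batch = NULL,
                         out_dir = NULL, alpha = 0.25, normalize = TRUE,
                         min_set_size = 5L, p_threshold = 0.05,
                         corr_p_threshold = 1e-4, k_clusters = 4L,
                         ties = c("low", "high"),
                         horizons = c(72, 96, 120), lfc_threshold = 0.5,
                         deg_p_threshold = 0.05, stromal_set = NULL,
                         immune_set = NULL, enrichment_sets = NULL,
                         n_perm = 1000L, seed = 1L) {
  ties <- match.arg(ties)
  surv <- check_surv(surv)
  stopifnot(is.matrix(expression), !is.null(colnames(expression)))

  ids <- intersect(colnames(expression), surv$sample_id)
  n_expr_only <- ncol(expression) - length(ids)
  n_surv_only <- nrow(surv) - length(ids)
  if (length(ids) < 4L)
    stop("fewer than 4 samples shared between expression and survival")
  if (n_expr_only + n_surv_only > 0)
    message("sample reconciliation: ", length(ids), " shared; dropped ",
            n_expr_only, " expression-only and ", n_surv_only,
            " survival-only sample(s)")
  expression <- expression[, ids, drop = FALSE]
  surv <- surv[match(ids, surv$sample_id), , drop = FALSE]

  if (!is.null(batch)) {
    if (!is.null(names(batch))) batch <- batch[ids]
    expression <- with_stage("batch_adjust", batch_adjust(expression, batch))
  }

  sets <- with_stage("restrict_signatures",
                     restrict_to_matrix(signatures, rownames(expression),
                                        min_size = min_set_size))
  enrich <- with_stage("ssgsea",
                       ssgsea_score(expression, sets, alpha = alpha,
                                    normalize = normalize))
  network <- with_stage("cell_correlations",
                        cell_correlations(enrich, corr_p_threshold))
  clusters <- with_stage("cluster_cells",
                         cluster_cells(enrich, k = min(k_clusters,
                                                       nrow(enrich))))
  built <- with_stage("tiics", build_tiics(enrich, surv, p_threshold,
                                           ties = ties))
  scores <- built$scores
  km <- with_stage("km_curve", km_curve(surv, scores$group))
  logrank <- with_stage("logrank", logrank_test(surv, scores$group))
  horizons_ok <- horizons[horizons <= max(surv$time_months) &
                            vapply(horizons, function(t)
                              any(surv$time_months <= t & surv$event == 1) &&
                                any(surv$time_months > t), logical(1))]
  auc <- if (length(horizons_ok))
    with_stage("compare_auc",
               compare_auc(scores$score, enrich, built$weights,
                           surv, horizons_ok))
  else NULL

  deg <- with_stage("moderated_t_deg",
                    moderated_t_deg(expression, scores$group,
                                    lfc_threshold, deg_p_threshold))

  out <- list(samples_used = ids, enrichment = enrich, network = network,
              clusters = clusters, screen = built$screen,
              weights = built$weights, scores = scores, km = km,
              logrank = logrank, auc = auc, deg = deg)

  if (!is.null(stromal_set) && !is.null(immune_set)) {
    est <- with_stage("estimate_scores",
                      estimate_scores(expression, stromal_set, immune_set))
    cmp <- lapply(c(stromal_score = "stromal_score",
                    immune_score = "immune_score",
                    estimate_score = "estimate_score",
                    tumor_purity = "tumor_purity"),
                  function(col) with_stage(paste0("group_compare:", col),
                                           group_compare(est[[col]],
                                                         scores$group)))
    out$estimate <- est
    out$estimate_comparisons <- cmp
  }
  if (!is.null(enrichment_sets)) {
    stat <- stats::setNames(deg$t, deg$gene)
    out$enrichment_sets_result <-
      with_stage("ranked_enrichment",
                 ranked_enrichment(stat, enrichment_sets, n_perm = n_perm,
                                   seed = seed))
  }

  if (!is.null(out_dir)) out$manifest <- write_pipeline_outputs(out, out_dir)
  out
}

#' Time-dependent AUC of the composite score versus single cell types
#'
#' One row per marker (the composite first, then each selected cell type's
#' enrichment row), one column per horizon. [time_dependent_auc()] treats
#' higher marker values as higher risk, so each marker is first oriented to
#' its risk direction: the composite is negated (high composite score means
#' lower hazard by construction), and a cell with screening HR < 1
#' (protective) contributes its negated enrichment row. AUCs are then
#' directly comparable as discrimination measures.
#'
#' @param tiics_score Per-sample composite score (aligned with `surv`).
#' @param enrich Cell types x samples enrichment matrix.
#' @param weights A `tiics_weights` data frame ([compute_weights()]): its
#'   `cell_type` rows are compared and its `HR` column orients them.
#' @param surv Survival data frame.
#' @param horizons Evaluation times in months.
#' @return Numeric matrix, (1 + nrow(weights)) x length(horizons).
#' @export
compare_auc <- function(tiics_score, enrich, weights, surv,
                        horizons = c(72, 96, 120)) {
  cells <- weights$cell_type
  stopifnot(all(cells %in% rownames(enrich)))
  orient <- ifelse(weights$HR < 1, -1, 1)
  rows <- rbind(TIICs = -tiics_score,
                enrich[cells, , drop = FALSE] * orient)
  out <- vapply(seq_len(nrow(rows)),
                function(i) time_dependent_auc(rows[i, ], surv, horizons),
                numeric(length(horizons)))
  out <- matrix(out, nrow = length(horizons))
  dimnames(out) <- list(paste0("t", horizons), rownames(rows))
  t(out)
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  write_expression_tsv(result$enrichment, p("enrichment.tsv"),
                       id_col = "cell_type")
  wt(result$network, "network.tsv")
  wt(data.frame(cell_type = names(result$clusters),
                cluster = result$clusters), "clusters.tsv")
  wt(result$screen$all, "cox_screen.tsv")
  wt(result$weights, "weights.tsv")
  wt(result$scores, "scores.tsv")
  wt(data.frame(metric = c("chi_square", "p_value"),
                value = c(result$logrank$chi_square,
                          result$logrank$p_value)), "logrank.tsv")
  if (!is.null(result$auc))
    wt(data.frame(score = rownames(result$auc), result$auc,
                  check.names = FALSE), "auc.tsv")
  wt(result$deg, "deg.tsv")
  if (!is.null(result$estimate)) wt(result$estimate, "estimate.tsv")
  if (!is.null(result$enrichment_sets_result))
    wt(result$enrichment_sets_result, "ranked_enrichment.tsv")
  files <- list.files(out_dir, full.names = TRUE)
  data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}
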