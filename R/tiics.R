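#' Screen cell types for prognostic association
#'
#' One univariate Cox proportional-hazards fit per cell type, regressing
#' survival on that cell's enrichment scores; cell types with Wald
#' p < `p_threshold` are selected, ordered by p-value.
#'
#' @param enrich Cell types x samples enrichment matrix; column names must
#'   match `surv$sample_id`.
#' @param surv Survival data frame (`sample_id`, `time_months`, `event`).
#' @param p_threshold Selection threshold on the Wald p-value; default 0.05.
#' @return List with `all` (a `cox_result`-style data frame with one row
#'   per cell type, plus a logical `selected` column) and `selected` (the
#'   selected rows, ordered by p-value). Errors if no cell passes.
#' @export
screen_cells <- function(enrich, surv, p_threshold = 0.05) {
  stopifnot(is.matrix(enrich))
  surv <- check_surv(surv)
  ids <- intersect(colnames(enrich), surv$sample_id)
  if (length(ids) < 3L) stop("fewer than 3 samples shared between ",
                             "enrichment matrix and survival table")
  enrich <- enrich[, ids, drop = FALSE]
  surv <- surv[match(ids, surv$sample_id), , drop = FALSE]
  rows <- lapply(rownames(enrich), function(cell) {
    r <- fit_cox(stats::setNames(data.frame(x = enrich[cell, ]), cell), surv)
    attr(r, "model") <- NULL
    r
  })
  all <- do.call(rbind, rows)
  names(all)[names(all) == "term"] <- "cell_type"
  all$selected <- all$p_value < p_threshold
  sel <- all[all$selected, , drop = FALSE]
  if (nrow(sel) == 0L)
    stop("no cell type passed the screen at p < ", p_threshold,
         "; the composite score is undefined on an empty selection ",
         "- review the threshold")
  sel <- sel[order(sel$p_value), , drop = FALSE]
  rownames(all) <- rownames(sel) <- NULL
  list(all = all, selected = sel, p_threshold = p_threshold)
}

#' Composite-score weights from screened Cox results
#'
#' The weight of each selected cell type is `(1 - HR) / SE(HR)`: protective
#' cells (HR < 1) get positive weights, harmful cells negative ones. SE(HR)
#' is by default the delta-method standard error `HR * se_beta`; set
#' `se = "beta"` to use the log-scale standard error instead (changes the
#' scale of the weights, never their sign).
#'
#' @param selected Data frame of screened cells with columns `cell_type`
#'   (or `term`), `HR`, `se_beta`, `se_HR`, `p_value`.
#' @param se Which standard error the denominator uses: `"HR"` (delta
#'   method, default) or `"beta"`.
#' @return Data frame of class `tiics_weights`: `cell_type`, `HR`, `se_HR`,
#'   `p_value`, `weight`.
#' @export
compute_weights <- function(selected, se = c("HR", "beta")) {
  se <- match.arg(se)
  if (!is.null(selected$cell_type)) cell <- selected$cell_type
  else if (!is.null(selected$term)) cell <- selected$term
  else stop("'selected' needs a cell_type or term column")
  if (nrow(selected) == 0L) stop("'selected' is empty")
  stopifnot(all(is.finite(selected$HR)), all(selected$HR > 0))
  denom <- if (se == "HR") selected$se_HR else selected$se_beta
  if (any(!is.finite(denom)) || any(denom <= 0))
    stop("standard errors must be finite and positive")
  out <- data.frame(cell_type = cell, HR = selected$HR, se_HR = selected$se_HR,
                    p_value = selected$p_value,
                    weight = (1 - selected$HR) / denom,
                    stringsAsFactors = FALSE)
  class(out) <- c("tiics_weights", class(out))
  rownames(out) <- NULL
  out
}

#' Compute the composite infiltration score (TIICs)
#'
#' Per-sample weighted sum of enrichment scores over the selected cell
#' types: `score_j = sum_i weight_i * ES[i, j]`.
#'
#' @param enrich Cell types x samples enrichment matrix; every weighted
#'   cell type must be present among its rows.
#' @param weights A `tiics_weights` data frame from [compute_weights()].
#' @return Data frame with `sample_id` and `score`.
#' @export
compute_tiics <- function(enrich, weights) {
  stopifnot(is.matrix(enrich))
  missing_cells <- setdiff(weights$cell_type, rownames(enrich))
  if (length(missing_cells))
    stop("cell type(s) absent from the enrichment matrix: ",
         paste(missing_cells, collapse = ", "))
  sc <- drop(crossprod(enrich[weights$cell_type, , drop = FALSE],
                       weights$weight))
  data.frame(sample_id = colnames(enrich), score = unname(sc),
             stringsAsFactors = FALSE)
}

#' Median stratification into high and low score groups
#'
#' The cohort median of the composite score is the cutoff; samples strictly
#' above it form the high group. Samples exactly at the median go to the
#' low group by default (`ties = "low"`), so that "high" always means
#' strictly above the cutoff; `ties = "high"` flips the convention.
#'
#' @param scores Data frame with `sample_id` and `score` (>= 2 samples).
#' @param ties Where samples tied with the median go: `"low"` (default) or
#'   `"high"`.
#' @return `scores` with an added `group` factor (levels `low`, `high`) and
#'   attribute `"cutoff"` (the median). Errors if all scores are identical.
#' @export
assign_groups <- function(scores, ties = c("low", "high")) {
  ties <- match.arg(ties)
  stopifnot(nrow(scores) >= 2L)
  if (diff(range(scores$score)) == 0)
    stop("all scores identical: no stratification possible")
  cutoff <- stats::median(scores$score)
  high <- if (ties == "low") scores$score > cutoff else scores$score >= cutoff
  scores$group <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Screen, weight, score and stratify in one call
#'
#' Convenience chain: [screen_cells()] -> [compute_weights()] ->
#' [compute_tiics()] -> [assign_groups()] on one cohort.
#'
#' @inheritParams screen_cells
#' @inheritParams compute_weights
#' @inheritParams assign_groups
#' @return List with `screen`, `weights`, `scores` (with groups and the
#'   median cutoff attribute).
#' @export
build_tiics <- function(enrich, surv, p_threshold = 0.05,
                        se = c("HR", "beta"), ties = c("low", "high")) {
  screen <- screen_cells(enrich, surv, p_threshold)
  weights <- compute_weights(screen$selected, se = match.arg(se))
  scores <- assign_groups(compute_tiics(enrich, weights),
                          ties = match.arg(ties))
  list(screen = screen, weights = weights, scores = scores)
}

#' Score an external validation cohort
#'
#' Applies the composite-score construction to an independent cohort. In
#' `"refit"` mode (default) the prognostic cells and weights are
#' re-estimated on the validation cohort itself — the score is "calculated
#' in the same way" as in training; in `"transfer"` mode the training
#' weights are reused unchanged. Either way the cohort is split at its own
#' median score and the two groups compared by log-rank test.
#'
#' @param enrich_val Cell types x samples enrichment matrix of the
#'   validation cohort (same signatures and scoring parameters as training).
#' @param surv_val Validation survival data (`sample_id`, `time_months`,
#'   `event`).
#' @param mode `"refit"` or `"transfer"`.
#' @param weights Training `tiics_weights`; required for `"transfer"`.
#' @param p_threshold Screening threshold used in refit mode.
#' @param ties Median tie convention, as in [assign_groups()].
#' @return List with `weights` (those actually applied), `scores` (with
#'   groups) and `logrank` (list `chi_square`, `p_value`).
#' @export
validate_external <- function(enrich_val, surv_val,
                              mode = c("refit", "transfer"), weights = NULL,
                              p_threshold = 0.05, ties = c("low", "high")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  surv_val <- check_surv(surv_val)
  if (mode == "refit") {
    built <- build_tiics(enrich_val, surv_val, p_threshold, ties = ties)
    weights <- built$weights
    scores <- built$scores
  } else {
    if (is.null(weights)) stop("'transfer' mode requires training weights")
    scores <- assign_groups(compute_tiics(enrich_val, weights), ties = ties)
  }
  m <- match(scores$sample_id, surv_val$sample_id)
  if (anyNA(m)) stop("scored sample(s) missing from the survival table")
  lr <- logrank_test(surv_val[m, , drop = FALSE], scores$group)
  list(weights = weights, scores = scores, logrank = lr)
}
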