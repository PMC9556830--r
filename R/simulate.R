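#' Simulation configuration for synthetic cohorts
#'
#' Defines the generative model for a synthetic bulk-expression cohort with
#' planted immune-cell signature sets and proportional-hazards survival.
#' Per cell type k and sample j a latent infiltration level a_kj ~ N(0,1) is
#' drawn; genes assigned to set k follow
#' `x_gj = mu_g + signal_strength * a_kj + batch effects + noise`, genes in
#' no set are pure noise around their baseline `mu_g ~ N(6, 1)` (a
#' log2-microarray-like scale). Event times are exponential with rate
#' `baseline_hazard * exp(sum_k beta_k * a_kj)`; censoring times are
#' exponential with their rate calibrated so the expected censored fraction
#' matches `censor_rate`.
#'
#' Defaults mirror a 28-signature immune deconvolution panel at a reduced
#' gene-space size that keeps simulation loops fast.
#'
#' @param n_genes Number of genes.
#' @param n_samples Number of samples.
#' @param n_cell_types Number of planted cell-type signature sets.
#' @param genes_per_set Genes per signature set
#'   (`n_cell_types * genes_per_set <= n_genes` required).
#' @param signal_strength Loading of the latent infiltration level on its
#'   set's genes (lambda; 0 = no signal).
#' @param noise_sd Residual gene-level noise standard deviation (sigma).
#' @param prognostic_cells Named or indexed numeric vector of log-hazard
#'   coefficients beta per prognostic cell; names/indices must lie in
#'   `1..n_cell_types`. Negative beta = protective cell. Empty = null cohort.
#' @param baseline_hazard Baseline event rate per month.
#' @param censor_rate Target expected fraction of censored samples, in \[0,1).
#' @param n_batches Number of pseudo-cohort batches (samples split evenly,
#'   in order).
#' @param batch_shift Additive location offset applied to batch 2.
#' @param batch_scale Multiplicative noise-scale factor applied to batch 2.
#' @param overlap_frac Fraction of each set's genes additionally shared with
#'   the next set (real signatures overlap; default 0 = disjoint sets).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_samples = 200L, n_cell_types = 28L,
                       genes_per_set = 20L, signal_strength = 1,
                       noise_sd = 1, prognostic_cells = numeric(0),
                       baseline_hazard = 0.01, censor_rate = 0.3,
                       n_batches = 1L, batch_shift = 0, batch_scale = 1,
                       overlap_frac = 0, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_cell_types = as.integer(n_cell_types),
              genes_per_set = as.integer(genes_per_set),
              signal_strength = signal_strength, noise_sd = noise_sd,
              prognostic_cells = prognostic_cells,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              n_batches = as.integer(n_batches), batch_shift = batch_shift,
              batch_scale = batch_scale, overlap_frac = overlap_frac,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, n_samples >= 1L, n_cell_types >= 1L,
              genes_per_set >= 1L, signal_strength >= 0, noise_sd > 0,
              baseline_hazard > 0, censor_rate >= 0, censor_rate < 1,
              n_batches >= 1L, batch_scale > 0,
              overlap_frac >= 0, overlap_frac < 1)
    if (n_cell_types * genes_per_set > n_genes)
      stop("infeasible config: n_cell_types * genes_per_set (",
           n_cell_types * genes_per_set, ") exceeds n_genes (", n_genes, ")")
  })
  if (length(cfg$prognostic_cells)) {
    idx <- prognostic_cell_indices(cfg)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > cfg$n_cell_types))
      stop("prognostic_cells must name/index cells within 1..n_cell_types")
    if (anyDuplicated(idx)) stop("duplicate prognostic cell")
  }
  structure(cfg, class = "sim_config")
}

cell_type_names <- function(n) sprintf("cell_%02d", seq_len(n))

# prognostic_cells keys may be integer indices ("3") or cell names
# ("cell_03"); an unnamed vector is taken as cells 1..length in order
prognostic_cell_indices <- function(config) {
  pc <- config$prognostic_cells
  nm <- names(pc)
  if (is.null(nm) || all(!nzchar(nm)))
    return(seq_along(pc))
  idx <- match(nm, cell_type_names(config$n_cell_types))
  miss <- is.na(idx)
  idx[miss] <- suppressWarnings(as.integer(nm[miss]))
  idx
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws expression, survival, signature sets and the underlying truth
#' (latent infiltration matrix, per-cell betas, batch labels, gene-to-set
#' assignment) under the model described in [sim_config()]. Bit-identical
#' given the same config (the seed lives in the config).
#'
#' @param config A [sim_config()].
#' @return A list of class `tiics_cohort` with elements `expression`
#'   (genes x samples numeric matrix, log scale), `survival` (data.frame
#'   `sample_id`, `time_months`, `event`), `signatures`
#'   (a [gene_set_collection()]), `batch` (per-sample integer batch labels)
#'   and `truth` (list: `latent` cells x samples, `betas`, `batch_labels`,
#'   `set_assignment`, `censor_hazard`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; n <- config$n_samples; K <- config$n_cell_types
  gps <- config$genes_per_set
  gene_ids <- sprintf("g%05d", seq_len(G))
  sample_ids <- sprintf("s%04d", seq_len(n))
  cells <- cell_type_names(K)

  # block assignment of the first K*gps genes to sets; rest unassigned
  assignment <- rep(NA_integer_, G)
  assignment[seq_len(K * gps)] <- rep(seq_len(K), each = gps)
  sets <- split(gene_ids[seq_len(K * gps)], assignment[seq_len(K * gps)])
  names(sets) <- cells
  n_ov <- floor(config$overlap_frac * gps)
  if (n_ov > 0L && K > 1L) {
    for (k in seq_len(K)) {
      nxt <- if (k == K) 1L else k + 1L
      sets[[k]] <- unique(c(sets[[k]], sets[[nxt]][seq_len(n_ov)]))
    }
  }
  signatures <- gene_set_collection(sets,
                                    rep("synthetic signature", K))

  batch <- sort(rep_len(seq_len(config$n_batches), n))
  latent <- matrix(rnorm(K * n), nrow = K, dimnames = list(cells, sample_ids))
  mu <- rnorm(G, mean = 6, sd = 1)

  sd_j <- config$noise_sd * ifelse(batch == 2L, config$batch_scale, 1)
  shift_j <- config$batch_shift * (batch == 2L)
  eps <- matrix(rnorm(G * n), nrow = G) * rep(sd_j, each = G)
  expr <- mu + eps
  in_block <- !is.na(assignment)
  expr[in_block, ] <- expr[in_block, , drop = FALSE] +
    config$signal_strength * latent[assignment[in_block], , drop = FALSE]
  expr <- expr + rep(shift_j, each = G)
  dimnames(expr) <- list(gene_ids, sample_ids)

  betas <- setNames(numeric(K), cells)
  if (length(config$prognostic_cells)) {
    idx <- prognostic_cell_indices(config)
    betas[idx] <- as.numeric(config$prognostic_cells)
  }
  lp <- drop(crossprod(latent, betas))
  rate <- config$baseline_hazard * exp(lp)
  etime <- stats::rexp(n, rate = rate)
  censor_hazard <- 0
  if (config$censor_rate > 0) {
    # P(censored | rate_i) = c / (c + rate_i); calibrate c so the mean hits
    # the target censored fraction
    f <- function(cc) mean(cc / (cc + rate)) - config$censor_rate
    upper <- max(rate) * 1e6
    censor_hazard <- stats::uniroot(f, c(1e-12, upper), tol = 1e-12)$root
    ctime <- stats::rexp(n, rate = censor_hazard)
  } else {
    ctime <- rep(Inf, n)
  }
  time <- pmin(etime, ctime)
  event <- as.integer(etime <= ctime)

  structure(list(
    expression = expr,
    survival = data.frame(sample_id = sample_ids, time_months = time,
                          event = event, stringsAsFactors = FALSE),
    signatures = signatures,
    batch = setNames(batch, sample_ids),
    truth = list(latent = latent, betas = betas,
                 batch_labels = setNames(batch, sample_ids),
                 set_assignment = setNames(assignment, gene_ids),
                 censor_hazard = censor_hazard)
  ), class = "tiics_cohort")
}

#' Write a cohort to plain-text files
#'
#' Serializes a generated cohort as TSV/GMT files re-readable by the
#' pipeline: `expression.tsv` (gene rows x sample columns),
#' `survival.tsv` (`sample_id`, `time_months`, `event`), `signatures.gmt`,
#' `batch.tsv`, and the ground truth (`truth_latent.tsv`,
#' `truth_assignment.tsv`, `truth_betas.tsv`).
#'
#' @param cohort A `tiics_cohort` from [generate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Data frame manifest (`file`, `path`), invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "tiics_cohort"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)
  write_expression_tsv(cohort$expression, p("expression.tsv"))
  utils::write.table(cohort$survival, p("survival.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$signatures, p("signatures.gmt"))
  utils::write.table(
    data.frame(sample_id = names(cohort$batch), batch = cohort$batch),
    p("batch.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_tsv(cohort$truth$latent, p("truth_latent.tsv"),
                       id_col = "cell_type")
  utils::write.table(
    data.frame(gene_id = names(cohort$truth$set_assignment),
               cell_type = ifelse(is.na(cohort$truth$set_assignment), "",
                                  cell_type_names(nrow(cohort$truth$latent))[
                                    cohort$truth$set_assignment])),
    p("truth_assignment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell_type = names(cohort$truth$betas),
               beta = cohort$truth$betas),
    p("truth_betas.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("expression.tsv", "survival.tsv", "signatures.gmt", "batch.tsv",
             "truth_latent.tsv", "truth_assignment.tsv", "truth_betas.tsv")
  invisible(data.frame(file = files, path = vapply(files, p, character(1)),
                       row.names = NULL))
}

#' Read / write an expression matrix as TSV
#'
#' First column holds the gene (row) id, remaining columns are samples.
#' Values round-trip at full double precision.
#'
#' @param matrix Numeric matrix with row and column names.
#' @param path File path.
#' @param id_col Name of the id column in the header.
#' @return `write_expression_tsv`: `path`, invisibly.
#'   `read_expression_tsv`: a numeric matrix.
#' @export
write_expression_tsv <- function(matrix, path, id_col = "gene_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a survival table from TSV
#'
#' Expects columns `sample_id`, `time_months`, `event` (0/1).
#'
#' @param path File path.
#' @return Data frame with the three columns.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_months", "event")
  if (!all(need %in% names(df)))
    stop("survival TSV must have columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df[need]
}
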