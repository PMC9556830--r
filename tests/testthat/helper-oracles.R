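# Independent reference implementations used as oracles. These deliberately
# follow the written-out definitions step by step (explicit loops, no shared
# code with the package internals).

# single-sample enrichment score of one set in one sample, by explicit
# double loop over positions
naive_ssgsea_es <- function(x, set, alpha) {
  ids <- names(x)
  r <- rank(x)
  ord <- order(-r, ids)
  rr <- r[ord]
  inset <- ids[ord] %in% set
  N <- length(x)
  s <- sum(inset)
  denom <- sum(rr[inset]^alpha)
  es <- 0
  for (i in seq_len(N)) {
    p_in <- sum(rr[seq_len(i)][inset[seq_len(i)]]^alpha) / denom
    p_out <- sum(!inset[seq_len(i)]) / (N - s)
    es <- es + (p_in - p_out)
  }
  es
}

# log partial likelihood of a univariate Cox model, no ties, written out
cox_log_pl <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# two-group log-rank chi-square by per-event-time O/E/V tabulation
naive_logrank_chisq <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  O1 <- E1 <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# plain binary ROC AUC (ties counted half)
binary_auc <- function(score, outcome) {
  pos <- score[outcome == 1]; neg <- score[outcome == 0]
  m <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(m)
}

# small expression matrix with named genes/samples
rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 6, 1), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

# exponential survival with a linear predictor, for direct survival tests
rand_surv <- function(n, lp = rep(0, n), h0 = 0.02, censor_hazard = 0.01) {
  et <- rexp(n, rate = h0 * exp(lp))
  ct <- if (censor_hazard > 0) rexp(n, rate = censor_hazard) else rep(Inf, n)
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             time_months = pmin(et, ct),
             event = as.integer(et <= ct))
}

write_tmp_gmt <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
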