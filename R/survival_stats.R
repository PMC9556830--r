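#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron handling of tied event times
#' (via the survival package), returning one row per covariate with the
#' log hazard ratio, HR, standard errors on both scales (the HR-scale SE is
#' the delta-method `HR * se_beta`) and a two-sided Wald p-value.
#'
#' @param covariates Numeric vector (univariate) or samples x p matrix /
#'   data frame; column names become term names.
#' @param surv Data frame with columns `time_months` (> 0) and `event`
#'   (0/1), one row per sample, aligned with `covariates`.
#' @return Data frame of class `cox_result`: `term`, `beta`, `HR`,
#'   `se_beta`, `se_HR`, `p_value`, `n_events`, `converged`. The fitted
#'   `survival::coxph` object is attached as attribute `"model"`.
#' @export
fit_cox <- function(covariates, surv) {
  surv <- check_surv(surv)
  X <- as.matrix(covariates)
  if (is.null(colnames(X)))
    colnames(X) <- if (ncol(X) == 1L) "x" else paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == nrow(surv))
  if (any(!is.finite(X))) stop("covariates must be finite")
  if (any(apply(X, 2, function(z) diff(range(z)) == 0)))
    stop("constant covariate(s): ",
         paste(colnames(X)[apply(X, 2, function(z) diff(range(z)) == 0)],
               collapse = ", "))
  n_events <- sum(surv$event)
  if (n_events < 2L)
    stop("need at least 2 observed events (got ", n_events, ")")
  df <- data.frame(X, check.names = FALSE)
  df$.time <- surv$time_months
  df$.event <- surv$event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  hr <- exp(beta)
  res <- data.frame(term = colnames(X), beta = beta, HR = hr,
                    se_beta = unname(se), se_HR = hr * unname(se),
                    p_value = 2 * stats::pnorm(-abs(beta / se)),
                    n_events = n_events, converged = converged,
                    stringsAsFactors = FALSE)
  class(res) <- c("cox_result", class(res))
  attr(res, "model") <- fit
  rownames(res) <- NULL
  res
}

check_surv <- function(surv) {
  need <- c("time_months", "event")
  if (!all(need %in% names(surv)))
    stop("survival data needs columns: ", paste(need, collapse = ", "))
  if (any(surv$time_months <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  surv
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate of the survival function for each group.
#'
#' @param surv Survival data frame (`time_months`, `event`).
#' @param group_labels Per-sample group labels (any atomic vector).
#' @return Named list (one element per group) of data frames with columns
#'   `time`, `n_risk`, `n_event`, `surv`; probabilities start at 1 and are
#'   non-increasing.
#' @export
km_curve <- function(surv, group_labels) {
  surv <- check_surv(surv)
  stopifnot(length(group_labels) == nrow(surv))
  g <- as.factor(group_labels)
  if (any(table(g) == 0L)) stop("empty group")
  out <- lapply(levels(g), function(lev) {
    s <- surv[g == lev, , drop = FALSE]
    fit <- survival::survfit(
      survival::Surv(time_months, event) ~ 1, data = s)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               surv = fit$surv)
  })
  names(out) <- levels(g)
  out
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events across event times with hypergeometric
#' variance; chi-square statistic on 1 degree of freedom.
#'
#' @param surv Survival data frame (`time_months`, `event`).
#' @param group_labels Per-sample labels taking exactly two values.
#' @return List with `chi_square` and `p_value`.
#' @export
logrank_test <- function(surv, group_labels) {
  surv <- check_surv(surv)
  g <- as.factor(group_labels)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) == 0L)) stop("empty group")
  if (sum(surv$event) < 1L) stop("no events observed")
  sd <- survival::survdiff(
    survival::Surv(time_months, event) ~ g,
    data = data.frame(surv, g = g))
  chisq <- unname(sd$chisq)
  list(chi_square = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Time-dependent (cumulative/dynamic) AUC under censoring
#'
#' Discrimination of a risk score for "event by time t" (cases: observed
#' events with time <= t) versus "survivor past t" (controls: time > t),
#' with inverse-probability-of-censoring weights from the Kaplan-Meier
#' estimate of the censoring distribution. Higher scores are taken to mean
#' higher risk. Without censoring this reduces exactly to the binary ROC
#' AUC for the event-by-t outcome.
#'
#' @param score Per-sample numeric risk score.
#' @param surv Survival data frame (`time_months`, `event`).
#' @param horizons Numeric vector of evaluation times (months); default the
#'   6/8/10-year horizons `c(72, 96, 120)`.
#' @return Named numeric vector of AUC(t), one per horizon.
#' @export
time_dependent_auc <- function(score, surv, horizons = c(72, 96, 120)) {
  surv <- check_surv(surv)
  stopifnot(length(score) == nrow(surv), all(is.finite(score)))
  tmax <- max(surv$time_months)
  if (any(horizons > tmax))
    stop("horizon(s) beyond the last observed time (", round(tmax, 2), "): ",
         paste(horizons[horizons > tmax], collapse = ", "))
  # censoring-distribution KM: G(t) right-continuous, G(t-) left-continuous
  cfit <- survival::survfit(
    survival::Surv(time_months, 1 - event) ~ 1, data = surv)
  Gright <- stats::stepfun(cfit$time, c(1, cfit$surv))
  Gleft <- stats::stepfun(cfit$time, c(1, cfit$surv), right = TRUE)
  clamp <- function(g) pmax(g, min(c(1, cfit$surv[cfit$surv > 0])))
  vapply(horizons, function(t) {
    case <- surv$time_months <= t & surv$event == 1
    ctrl <- surv$time_months > t
    if (!any(case)) stop("no events before horizon ", t)
    if (!any(ctrl)) stop("no survivors past horizon ", t)
    wi <- 1 / clamp(Gleft(surv$time_months[case]))
    wj <- rep(1 / clamp(Gright(t)), sum(ctrl))
    sc <- score[case]; st <- score[ctrl]
    conc <- outer(sc, st, ">") + 0.5 * outer(sc, st, "==")
    sum((wi %o% wj) * conc) / (sum(wi) * sum(wj))
  }, numeric(1), USE.NAMES = FALSE) -> auc
  names(auc) <- paste0("t", horizons)
  auc
}

#' Predicted survival probabilities from a fitted Cox model
#'
#' Breslow baseline cumulative hazard H0(t) from the fitted model;
#' per-sample survival `S(t|x) = exp(-H0(t) * exp(x'beta))`.
#'
#' @param cox A `cox_result` from [fit_cox()] (its attached model is used).
#' @param covariates New samples x p matrix on the same terms the model was
#'   fitted with.
#' @param horizons Evaluation times in months; default `c(72, 96, 120)`
#'   (6, 8 and 10 years). Must lie within the observed time range.
#' @return Samples x horizons matrix of survival probabilities in (0, 1],
#'   non-increasing along each row.
#' @export
predict_survival <- function(cox, covariates, horizons = c(72, 96, 120)) {
  model <- attr(cox, "model")
  if (is.null(model)) stop("'cox' carries no fitted model; use fit_cox()")
  X <- as.matrix(covariates)
  stopifnot(ncol(X) == length(stats::coef(model)))
  tmax <- max(model$y[, "time"])
  if (any(horizons > tmax))
    stop("horizon(s) beyond the observed time range: ",
         paste(horizons[horizons > tmax], collapse = ", "))
  bh <- survival::basehaz(model, centered = FALSE)
  H0 <- stats::stepfun(bh$time, c(0, bh$hazard))
  lp <- drop(X %*% stats::coef(model))
  out <- outer(exp(lp), H0(horizons), function(risk, h) exp(-h * risk))
  dimnames(out) <- list(rownames(X), paste0("t", horizons))
  out
}
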