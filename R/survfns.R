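#' Recurrence analysis window
#'
#' Standard windows used in early/late recurrence dissociation analyses:
#' overall, early (0, tau], very_early (0, 12), intermediate (12, 24],
#' and late (tau, Inf). \code{late} generalizes to landmark times beyond
#' 24 months (e.g. 36, 48) via \code{tau}.
#'
#' @param kind one of overall, early, very_early, intermediate, late.
#' @param tau changepoint in months (default 24) for early/late.
#' @return object of class \code{hir_window} with fields \code{kind},
#'   \code{lo} (landmark entry) and \code{hi} (truncation time).
#' @export
recurrence_window <- function(kind = c("overall", "early", "very_early",
                                       "intermediate", "late"),
                              tau = 24) {
  kind <- match.arg(kind)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  b <- switch(kind,
              overall = c(0, Inf),
              early = c(0, tau),
              very_early = c(0, 12),
              intermediate = c(12, 24),
              late = c(tau, Inf))
  structure(list(kind = kind, lo = b[1], hi = b[2]), class = "hir_window")
}

#' Restrict a clinical table to a recurrence window
#'
#' Early-type windows (lo = 0): events after \code{hi} are recoded as
#' censored at \code{hi} and follow-up is truncated there. Late-type
#' windows (lo > 0) are landmark analyses: only patients event-free and
#' still under observation at \code{lo} are retained, the clock stays at
#' surgery, and an \code{entry} column records the delayed entry at
#' \code{lo} (events beyond \code{hi}, if finite, are again censored at
#' \code{hi}). A naive mode instead restarts the clock at \code{lo}.
#'
#' @param clinical a \code{\link{clinical_table}}.
#' @param window a \code{\link{recurrence_window}}.
#' @param mode \code{"landmark"} (default) or \code{"restart"}.
#' @return a clinical table with adjusted \code{time_months},
#'   \code{event}, and (landmark mode) \code{entry}.
#' @export
window_subset <- function(clinical, window, mode = c("landmark", "restart")) {
  stopifnot(inherits(window, "hir_window"))
  mode <- match.arg(mode)
  df <- as.data.frame(clinical)
  if (window$lo > 0) {
    df <- df[df$time_months > window$lo, , drop = FALSE]
    if (mode == "landmark") df$entry <- rep(window$lo, nrow(df))
    else df$time_months <- df$time_months - window$lo
  }
  hi <- if (mode == "restart" && window$lo > 0) window$hi - window$lo
        else window$hi
  if (is.finite(hi)) {
    over <- df$time_months > hi
    df$event[over] <- 0L
    df$time_months[over] <- hi
  }
  rownames(df) <- NULL
  clinical_table(df)
}

surv_obj <- function(clinical) {
  df <- as.data.frame(clinical)
  if ("entry" %in% names(df))
    survival::Surv(df$entry, df$time_months, df$event)
  else survival::Surv(df$time_months, df$event)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with censoring marks, plus median follow-up
#' computed by reverse Kaplan-Meier (censoring distribution).
#'
#' @param clinical a \code{\link{clinical_table}}.
#' @param groups vector of group labels aligned to patients.
#' @return list: \code{fit} (a \code{survfit}), \code{curves}
#'   (data.frame group/time/n_risk/surv/censored),
#'   \code{median_followup_months}.
#' @export
km_estimate <- function(clinical, groups = NULL) {
  df <- as.data.frame(clinical)
  if (is.null(groups)) groups <- rep("all", nrow(df))
  if (any(table(groups) == 0) || nrow(df) == 0)
    stop("empty group", call. = FALSE)
  g <- factor(groups)
  fit <- survival::survfit(surv_obj(clinical) ~ g)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time))
         else sub("^g=", "", as.character(s$strata))
  curves <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                       surv = s$surv, censored = s$n.censor > 0)
  rev_fit <- survival::survfit(
    survival::Surv(df$time_months, 1L - df$event) ~ 1)
  mf <- unname(summary(rev_fit)$table["median"])
  list(fit = fit, curves = curves, median_followup_months = mf)
}

#' Log-rank test
#'
#' @param clinical a \code{\link{clinical_table}}.
#' @param groups group labels (2 or more groups).
#' @return list: \code{chi2}, \code{df}, \code{p}.
#' @export
logrank_test <- function(clinical, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  df <- as.data.frame(clinical)
  if ("entry" %in% names(df)) {
    # a common landmark entry leaves log-rank risk sets unchanged
    if (length(unique(df$entry)) > 1L)
      stop("log-rank with heterogeneous delayed entry not supported; ",
           "use cox_fit", call. = FALSE)
    df$entry <- NULL
  }
  sd <- survival::survdiff(
    survival::Surv(df$time_months, df$event) ~ g)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit with Wald intervals
#'
#' Fits recurrence-free survival on the listed covariates (columns of
#' the clinical table) using Efron tie handling. Patients with missing
#' values in any requested covariate — notably missing BCLC stage — are
#' excluded. BCLC is automatically recoded to the standard dichotomy
#' 0/A vs B/C when requested by name.
#'
#' @param clinical a \code{\link{clinical_table}} (possibly from
#'   \code{\link{window_subset}}, landmark entry respected).
#' @param covariates character vector of column names.
#' @return data.frame of class \code{hir_survfit}: \code{term},
#'   \code{hr}, \code{lo}, \code{hi}, \code{p}; attributes \code{n_used},
#'   \code{events_used}.
#' @export
cox_fit <- function(clinical, covariates) {
  df <- as.data.frame(clinical)
  if (sum(df$event) < 1) stop("need at least one event", call. = FALSE)
  if ("bclc" %in% covariates) {
    df$bclc_bc <- ifelse(is.na(df$bclc), NA,
                         as.integer(df$bclc %in% c("B", "C")))
    covariates[covariates == "bclc"] <- "bclc_bc"
  }
  miss <- setdiff(covariates, names(df))
  if (length(miss))
    stop("unknown covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(df[covariates])
  df <- df[keep, , drop = FALSE]
  fml <- stats::as.formula(paste("surv_obj(df) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w)))
        stop("Cox fit did not converge (possible separation): ",
             conditionMessage(w), call. = FALSE)
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  sm <- summary(fit)
  out <- data.frame(term = rownames(sm$coefficients),
                    hr = sm$coefficients[, "exp(coef)"],
                    lo = sm$conf.int[, "lower .95"],
                    hi = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  attr(out, "n_used") <- fit$n
  attr(out, "events_used") <- fit$nevent
  class(out) <- c("hir_survfit", "data.frame")
  out
}
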