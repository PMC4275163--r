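#' Weighted Cox-score risk model
#'
#' A risk classifier of the form used by published tumor signatures: each
#' gene carries a fixed weight (typically its Cox score from the original
#' training cohort), a patient's score is the weighted sum of centered
#' expression, and patients are called high/low risk against reference
#' thresholds — the lowest score observed in the reference poor-prognosis
#' group (above it: high risk) and the highest score of the reference
#' good-prognosis group (below it: low risk). Scores falling between the
#' thresholds are indeterminate unless a strict two-group call is
#' requested.
#'
#' @param gene_weights named numeric vector, names are gene symbols.
#' @param high_threshold,low_threshold reference score cutoffs; may be NA
#'   until set (e.g. via a median split).
#' @param name model label.
#' @return object of class \code{hir_riskmodel}.
#' @export
risk_score_model <- function(gene_weights, high_threshold = NA_real_,
                             low_threshold = NA_real_, name = "risk") {
  if (is.null(names(gene_weights)))
    stop("gene_weights must be named by symbol", call. = FALSE)
  if (!is.na(high_threshold) && !is.na(low_threshold) &&
      low_threshold > high_threshold)
    stop("low_threshold must not exceed high_threshold", call. = FALSE)
  structure(list(gene_weights = gene_weights,
                 high_threshold = high_threshold,
                 low_threshold = low_threshold, name = name),
            class = "hir_riskmodel")
}

#' Weighted risk score for each sample
#'
#' \eqn{score = \sum_g w_g x_g} over the model genes present in the
#' (centered) expression matrix; absent genes are reported via the
#' \code{absent} attribute.
#'
#' @param model an \code{\link{risk_score_model}}.
#' @param x centered \code{\link{expression_matrix}} (rows named by
#'   symbol, as returned by \code{\link{match_and_center}}).
#' @return named numeric scores with attribute \code{absent}.
#' @export
weighted_score <- function(model, x) {
  stopifnot(inherits(model, "hir_riskmodel"), inherits(x, "hir_expr"))
  present <- intersect(names(model$gene_weights), feature_ids(x))
  if (!length(present))
    stop("no model genes present in expression matrix", call. = FALSE)
  w <- model$gene_weights[present]
  s <- as.numeric(crossprod(x$values[present, , drop = FALSE], w))
  names(s) <- sample_ids(x)
  attr(s, "absent") <- setdiff(names(model$gene_weights), present)
  s
}

#' Dichotomize risk scores against reference thresholds
#'
#' @param model an \code{\link{risk_score_model}} with thresholds set.
#' @param scores named numeric scores.
#' @param strict if TRUE (default), scores between thresholds are
#'   \code{indeterminate}; otherwise they are assigned to the nearer
#'   threshold's group.
#' @return data.frame: \code{patient_id}, \code{score}, \code{group}.
#' @export
classify_by_thresholds <- function(model, scores, strict = TRUE) {
  stopifnot(inherits(model, "hir_riskmodel"))
  if (is.na(model$high_threshold) || is.na(model$low_threshold))
    stop("model thresholds are not set", call. = FALSE)
  grp <- ifelse(scores > model$high_threshold, "high",
         ifelse(scores < model$low_threshold, "low", "indeterminate"))
  if (!strict) {
    mid <- grp == "indeterminate"
    grp[mid] <- ifelse(abs(scores[mid] - model$high_threshold) <=
                       abs(scores[mid] - model$low_threshold),
                       "high", "low")
  }
  data.frame(patient_id = names(scores) %||% seq_along(scores),
             score = as.numeric(scores), group = grp)
}

#' Integrate two predictors into three risk strata
#'
#' Combines an HIR/QT subgroup call (adjacent tissue) with a high/low
#' tumor risk call: HIR plus high risk is the worst stratum, QT plus low
#' risk the best, and the two discordant combinations form an
#' intermediate stratum. Patients missing either call are excluded and
#' listed.
#'
#' @param hir_labels named character vector ("HIR"/"QT") by patient.
#' @param risk_groups named character vector ("high"/"low") by patient.
#' @return data.frame \code{patient_id}, \code{stratum} in
#'   \{HIR-high, intermediate, QT-low\}; attribute \code{excluded}.
#' @export
integrate_predictors <- function(hir_labels, risk_groups) {
  ids <- union(names(hir_labels), names(risk_groups))
  common <- intersect(names(hir_labels), names(risk_groups))
  common <- common[!is.na(hir_labels[common]) & !is.na(risk_groups[common])]
  h <- hir_labels[common]; r <- risk_groups[common]
  stratum <- ifelse(h == "HIR" & r == "high", "HIR-high",
             ifelse(h == "QT" & r == "low", "QT-low", "intermediate"))
  out <- data.frame(patient_id = common, stratum = stratum)
  attr(out, "excluded") <- setdiff(ids, common)
  out
}

#' Cramer's V concordance for a 2x2 table
#'
#' \eqn{V = \sqrt{\chi^2 / n}} for a 2x2 table (where
#' \eqn{\min(r-1,c-1)=1}). The chi-squared statistic uses the Yates
#' continuity correction by default; a Fisher exact p-value is also
#' returned for small tables.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param correct apply continuity correction (default TRUE).
#' @return list: \code{v}, \code{chi2}, \code{p_chi2}, \code{p_fisher},
#'   \code{n}.
#' @export
cramers_v <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || sum(tab) == 0)
    stop("counts must be nonnegative with positive total", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: Cramer's V undefined", call. = FALSE)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  fi <- stats::fisher.test(tab)
  list(v = sqrt(unname(cs$statistic) / sum(tab)),
       chi2 = unname(cs$statistic), p_chi2 = cs$p.value,
       p_fisher = fi$p.value, n = sum(tab))
}

#' Cross-tabulate two binary call vectors and measure concordance
#'
#' Builds the 2x2 table over common patients and delegates to
#' \code{\link{cramers_v}}.
#'
#' @param calls_a,calls_b named character vectors of binary calls.
#' @param correct continuity correction flag.
#' @return list as in \code{\link{cramers_v}} plus \code{table}.
#' @export
model_concordance <- function(calls_a, calls_b, correct = TRUE) {
  common <- intersect(names(calls_a), names(calls_b))
  if (length(common) < 2)
    stop("need at least 2 common patients", call. = FALSE)
  tab <- table(calls_a[common], calls_b[common])
  if (!all(dim(tab) == c(2L, 2L)))
    stop("calls must each take exactly 2 values on common patients",
         call. = FALSE)
  res <- cramers_v(unclass(tab)[seq_len(2), seq_len(2)], correct = correct)
  res$table <- tab
  res
}
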