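#' Compound covariate
#'
#' Collapses a sample's signature-gene expression into one score: the
#' weighted sum \eqn{c = \sum_g w_g x_g} with weights equal to the
#' training t-statistics. All downstream classification operates on this
#' single covariate.
#'
#' @param weights named numeric vector (names = feature IDs or symbols).
#' @param expr_col named numeric vector of expression for one sample, or
#'   a matrix with features in rows (one score per column).
#' @return numeric score(s).
#' @export
compound_covariate <- function(weights, expr_col) {
  if (is.null(names(weights))) stop("weights must be named", call. = FALSE)
  if (is.matrix(expr_col)) {
    miss <- setdiff(names(weights), rownames(expr_col))
    if (length(miss))
      stop("missing feature(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    return(as.numeric(crossprod(expr_col[names(weights), , drop = FALSE],
                                weights)))
  }
  miss <- setdiff(names(weights), names(expr_col))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "), call. = FALSE)
  sum(weights * expr_col[names(weights)])
}

#' Train a Bayesian compound covariate predictor
#'
#' Computes the compound covariate of every training sample, then models
#' it with class-conditional Gaussians: per-class means of c, a pooled
#' within-class variance, and class priors (equal by default, so cohort
#' composition does not leak into the posterior).
#'
#' @param x training \code{\link{expression_matrix}} (e.g. pre/post
#'   injury biopsies).
#' @param labels factor-like with levels QT/HIR (any two labels; the
#'   second sorted level is treated as HIR unless labels are literally
#'   "HIR"/"QT").
#' @param weights named numeric vector of feature weights.
#' @param priors length-2 numeric summing to 1, (p_HIR, p_QT).
#' @param threshold posterior cutoff for calling HIR (default 0.5).
#' @return object of class \code{hir_bccp} with fields \code{weights},
#'   \code{class_means} (named HIR/QT), \code{pooled_variance},
#'   \code{priors}, \code{threshold}.
#' @export
train_bccp <- function(x, labels, weights, priors = c(0.5, 0.5),
                       threshold = 0.5) {
  stopifnot(inherits(x, "hir_expr"))
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2)
    stop("training labels must contain exactly two classes; got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  hir_lv <- if ("HIR" %in% lv) "HIR" else lv[2L]
  qt_lv <- setdiff(lv, hir_lv)
  if (any(table(labels) < 2))
    stop("each class needs at least 2 training samples", call. = FALSE)
  if (abs(sum(priors) - 1) > 1e-8 || any(priors <= 0))
    stop("priors must be positive and sum to 1", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0,1)", call. = FALSE)
  cc <- compound_covariate(weights, x$values)
  m_hir <- mean(cc[labels == hir_lv])
  m_qt <- mean(cc[labels == qt_lv])
  n1 <- sum(labels == hir_lv); n2 <- sum(labels == qt_lv)
  V <- (sum((cc[labels == hir_lv] - m_hir)^2) +
        sum((cc[labels == qt_lv] - m_qt)^2)) / (n1 + n2 - 2)
  if (V <= 0) stop("zero pooled variance: classes are degenerate",
                   call. = FALSE)
  structure(list(weights = weights,
                 class_means = c(HIR = m_hir, QT = m_qt),
                 pooled_variance = V,
                 priors = c(HIR = priors[1], QT = priors[2]),
                 threshold = threshold,
                 feature_order = names(weights)),
            class = "hir_bccp")
}

#' Posterior probability of the HIR class
#'
#' \eqn{P(\mathrm{HIR}\mid c) = p_H \phi(c; m_H, V) / (p_H \phi(c; m_H,
#' V) + p_Q \phi(c; m_Q, V))} with the model's pooled variance. Computed
#' on the log scale, so it is finite for any real c.
#'
#' @param model an \code{hir_bccp}.
#' @param cc numeric compound covariate value(s).
#' @return probabilities in [0,1].
#' @export
posterior_hir <- function(model, cc) {
  stopifnot(inherits(model, "hir_bccp"))
  sdv <- sqrt(model$pooled_variance)
  lh <- stats::dnorm(cc, model$class_means["HIR"], sdv, log = TRUE) +
    log(model$priors["HIR"])
  lq <- stats::dnorm(cc, model$class_means["QT"], sdv, log = TRUE) +
    log(model$priors["QT"])
  unname(1 / (1 + exp(lq - lh)))
}

#' Classify a cohort into HIR / QT subgroups
#'
#' Expects expression already restricted to signature genes and centered
#' per cohort (\code{\link{match_and_center}}); weights are matched by
#' name and features absent from the cohort are dropped with a warning
#' when coverage falls below 50% (error at zero coverage).
#'
#' @param model an \code{hir_bccp}.
#' @param x cohort \code{\link{expression_matrix}}.
#' @return data.frame: \code{sample_id}, \code{compound_covariate},
#'   \code{prob_hir}, \code{label}; attribute \code{counts} holds the
#'   per-subgroup tally.
#' @export
classify_cohort <- function(model, x) {
  stopifnot(inherits(model, "hir_bccp"), inherits(x, "hir_expr"))
  present <- intersect(model$feature_order, feature_ids(x))
  if (!length(present))
    stop("no model features present in cohort", call. = FALSE)
  cov <- length(present) / length(model$feature_order)
  if (cov < 0.5)
    warning(sprintf("only %.0f%% of model features present in cohort",
                    100 * cov))
  w <- model$weights[present]
  cc <- compound_covariate(w, x$values)
  p <- posterior_hir(model, cc)
  out <- data.frame(sample_id = sample_ids(x), compound_covariate = cc,
                    prob_hir = p,
                    label = ifelse(p > model$threshold, "HIR", "QT"))
  attr(out, "counts") <- table(factor(out$label, c("HIR", "QT")))
  out
}

#' Leave-one-out cross-validation of the BCCP
#'
#' Each sample is predicted by a model trained on all other samples.
#' With \code{weights_recompute = TRUE} the t-statistic weights are also
#' refit within each fold (honest cross-validation): the fold's held-out
#' sample contributes neither to the class Gaussians nor to the weights.
#'
#' @param x training \code{\link{expression_matrix}}.
#' @param labels two-class labels over samples.
#' @param weights named weights used when \code{weights_recompute} is
#'   FALSE.
#' @param weights_recompute refit weights per fold from a two-class
#'   random-variance t-test.
#' @param priors,threshold passed to \code{\link{train_bccp}}.
#' @return list: \code{predictions} (per-sample held-out posterior and
#'   label), \code{error_rate}, \code{skipped_folds}.
#' @export
bccp_loocv <- function(x, labels, weights = NULL, weights_recompute = FALSE,
                       priors = c(0.5, 0.5), threshold = 0.5) {
  stopifnot(inherits(x, "hir_expr"))
  labels <- as.character(labels)
  n <- ncol(x$values)
  if (n < 3) stop("need at least 3 samples for LOOCV", call. = FALSE)
  if (!weights_recompute && is.null(weights))
    stop("supply weights or set weights_recompute = TRUE", call. = FALSE)
  preds <- data.frame(sample_id = sample_ids(x),
                      prob_hir = NA_real_, label = NA_character_)
  skipped <- character(0)
  for (i in seq_len(n)) {
    lab_tr <- labels[-i]
    if (length(unique(lab_tr)) < 2 || any(table(lab_tr) < 2)) {
      skipped <- c(skipped, sample_ids(x)[i])
      next
    }
    xtr <- expression_matrix(x$values[, -i, drop = FALSE],
                             feature_ids(x), x$gene_symbols,
                             sample_ids(x)[-i])
    w <- if (weights_recompute) {
      tb <- random_variance_ttest(xtr, lab_tr)
      stats::setNames(tb$t_stat, tb$feature_id)
    } else weights
    mod <- train_bccp(xtr, lab_tr, w, priors = priors,
                      threshold = threshold)
    cc <- compound_covariate(mod$weights, x$values[, i])
    p <- posterior_hir(mod, cc)
    preds$prob_hir[i] <- p
    preds$label[i] <- if (p > threshold) "HIR" else "QT"
  }
  hir_lv <- if ("HIR" %in% labels) "HIR" else sort(unique(labels))[2L]
  truth <- ifelse(labels == hir_lv, "HIR", "QT")
  ok <- !is.na(preds$label)
  list(predictions = preds,
       error_rate = mean(preds$label[ok] != truth[ok]),
       skipped_folds = skipped)
}

#' Write BCCP predictions as TSV / model as JSON
#' @param model an \code{hir_bccp}; \code{path} output path.
#' @param path file path.
#' @export
write_bccp <- function(model, path) {
  jsonlite::write_json(
    list(weights = as.list(model$weights),
         class_means = as.list(model$class_means),
         pooled_variance = model$pooled_variance,
         priors = as.list(model$priors), threshold = model$threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
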