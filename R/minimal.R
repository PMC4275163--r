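#' Nearest shrunken centroid (PAM-style) classifier
#'
#' Standardized class-centroid deviations
#' \eqn{d_{gk} = (\bar x_{gk} - \bar x_g) / (m_k (s_g + s_0))} are
#' soft-thresholded, \eqn{d'_{gk} = \mathrm{sign}(d_{gk})(|d_{gk}| -
#' \Delta)_+}, shrinking per-class centroids toward the overall centroid
#' and zeroing out uninformative genes. Classification minimizes the
#' standardized squared distance to the shrunken centroids minus
#' \eqn{2\log\pi_k}. A k-fold stratified cross-validated miscalculation
#' rate is reported for every \eqn{\Delta} on the grid; at full
#' shrinkage (no surviving features) the classifier falls back to the
#' largest prior.
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param labels two-class labels over samples.
#' @param delta_grid nonnegative shrinkage thresholds (default: 30 values
#'   from 0 to the largest |d|).
#' @param cv_folds folds for the error curve (default 10, capped at the
#'   smaller class size).
#' @param seed RNG seed for fold assignment.
#' @param priors class prior probabilities (default empirical).
#' @return list of class \code{hir_nsc}: \code{deltas},
#'   \code{n_surviving}, \code{cv_error}, \code{models} (per-delta
#'   shrunken centroids), \code{stats} (centroids, s_g, s0).
#' @export
nsc_fit <- function(x, labels, delta_grid = NULL, cv_folds = 10L,
                    seed = 1L, priors = NULL) {
  stopifnot(inherits(x, "hir_expr"))
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("need exactly two classes", call. = FALSE)
  if (any(table(labels) < 3))
    stop("need at least 3 samples per class", call. = FALSE)
  st <- nsc_stats(x$values, labels)
  if (is.null(priors)) priors <- as.numeric(table(labels)) / length(labels)
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(st$d)), length.out = 30L)
  if (any(delta_grid < 0)) stop("delta must be nonnegative", call. = FALSE)
  delta_grid <- sort(delta_grid)

  models <- lapply(delta_grid, function(dl) nsc_shrink(st, dl, priors))
  n_surv <- vapply(models, function(m) m$n_surviving, 1L)

  # stratified CV folds, fixed by seed
  k <- min(cv_folds, min(table(labels)))
  folds <- with_substream(seed, 7L, expr = {
    f <- integer(length(labels))
    for (lv in levels(labels)) {
      i <- which(labels == lv)
      f[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    f
  })
  cv_err <- numeric(length(delta_grid))
  for (fold in seq_len(k)) {
    te <- folds == fold
    st_tr <- nsc_stats(x$values[, !te, drop = FALSE], droplevels(labels[!te]))
    for (j in seq_along(delta_grid)) {
      m <- nsc_shrink(st_tr, delta_grid[j], priors)
      pred <- nsc_predict_core(m, x$values[, te, drop = FALSE])
      cv_err[j] <- cv_err[j] + sum(pred != as.character(labels[te]))
    }
  }
  cv_err <- cv_err / length(labels)
  structure(list(deltas = delta_grid, n_surviving = n_surv,
                 cv_error = cv_err, models = models, stats = st,
                 labels = levels(labels)),
            class = "hir_nsc")
}

nsc_stats <- function(v, labels) {
  labels <- factor(labels)
  K <- nlevels(labels); n <- ncol(v)
  xbar <- rowMeans(v)
  cent <- sapply(levels(labels), function(lv)
    rowMeans(v[, labels == lv, drop = FALSE]))
  ss <- 0
  for (lv in levels(labels)) {
    i <- labels == lv
    ss <- ss + rowSums((v[, i, drop = FALSE] - cent[, lv])^2)
  }
  s <- sqrt(ss / (n - K))
  s0 <- stats::median(s)
  nk <- as.numeric(table(labels))
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(cent - xbar, 1L, s + s0, "/")
  d <- sweep(d, 2L, mk, "/")
  list(xbar = xbar, cent = cent, s = s, s0 = s0, mk = mk, d = d,
       classes = levels(labels))
}

nsc_shrink <- function(st, delta, priors) {
  dprime <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  shrunk <- st$xbar + sweep(sweep(dprime, 2L, st$mk, "*"),
                            1L, st$s + st$s0, "*")
  surv <- rowSums(dprime != 0) > 0
  list(delta = delta, centroids = shrunk, surviving = which(surv),
       n_surviving = sum(surv), s = st$s, s0 = st$s0,
       priors = priors, classes = st$classes)
}

nsc_predict_core <- function(m, v) {
  if (m$n_surviving == 0)
    return(rep(m$classes[which.max(m$priors)], ncol(v)))
  g <- m$surviving
  sc <- (m$s + m$s0)[g]
  disc <- sapply(seq_along(m$classes), function(k)
    colSums(((v[g, , drop = FALSE] - m$centroids[g, k]) / sc)^2) -
      2 * log(m$priors[k]))
  if (!is.matrix(disc)) disc <- matrix(disc, nrow = 1L)
  m$classes[apply(disc, 1L, which.min)]
}

#' Predict classes from a fitted NSC model at a chosen delta
#'
#' @param object an \code{hir_nsc} fit.
#' @param x an \code{\link{expression_matrix}} with the training features.
#' @param delta which shrinkage threshold to use (must be on the grid).
#' @param ... unused.
#' @return character vector of class labels.
#' @export
predict.hir_nsc <- function(object, x, delta = 0, ...) {
  j <- which(abs(object$deltas - delta) < 1e-12)[1L]
  if (is.na(j)) stop("delta not on the fitted grid", call. = FALSE)
  nsc_predict_core(object$models[[j]], x$values)
}

#' Select a fixed-size gene panel stratified by functional category
#'
#' Picks \code{per_category} features at random from each of the 10
#' largest categories (ties broken alphabetically), reproducibly under
#' the given seed — the construction behind compact panels such as a
#' 20-gene (10 categories x 2) model.
#'
#' @param signature an \code{\link{hir_signature}}.
#' @param categories named character vector: feature_id -> category.
#' @param per_category features drawn per category (default 2).
#' @param n_categories number of categories used (default 10).
#' @param seed RNG seed.
#' @return character vector of selected feature IDs with attribute
#'   \code{selection} (data.frame feature_id, category).
#' @export
select_by_category <- function(signature, categories, per_category = 2L,
                               n_categories = 10L, seed = 1L) {
  feats <- signature_features(signature)$feature_id
  categories <- categories[names(categories) %in% feats]
  sizes <- sort(table(categories), decreasing = TRUE)
  eligible <- names(sizes)[sizes >= per_category]
  if (length(eligible) < n_categories) {
    small <- setdiff(names(sizes), eligible)
    stop(sprintf("need %d categories with >=%d members; too small: %s",
                 n_categories, per_category,
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  use <- sort(eligible[order(-sizes[eligible], eligible)][seq_len(n_categories)])
  picks <- with_substream(seed, 8L, expr = {
    unlist(lapply(use, function(cat) {
      pool <- sort(names(categories)[categories == cat])
      pool[sample.int(length(pool), per_category)]
    }))
  })
  sel <- data.frame(feature_id = picks,
                    category = rep(use, each = per_category))
  structure(picks, selection = sel)
}

#' Univariate screen plus backward stepwise gene selection
#'
#' Stage 1 screens every signature gene with a univariate Cox model of
#' recurrence-free survival, keeping genes with Wald p <
#' \code{screen_alpha}. Stage 2 fits a joint model of the screened genes
#' and removes the largest-p term one at a time (ties broken by feature
#' ID) until every remaining term satisfies p < \code{retain_alpha}.
#' Either stage can use a Cox or a logistic (recurrence by end of
#' follow-up) model; the default screens with Cox and eliminates with
#' logistic. Perfectly collinear genes yield NA coefficients and are
#' dropped with a warning.
#'
#' @param x an \code{\link{expression_matrix}} (signature genes).
#' @param clinical a \code{\link{clinical_table}} aligned to samples.
#' @param screen_alpha univariate threshold (default 0.005).
#' @param retain_alpha backward-elimination threshold (default 0.1).
#' @param screen_family,final_family \code{"cox"} or \code{"logistic"}.
#' @return list of class \code{hir_stepwise}: \code{screened_features},
#'   \code{selected_features}, \code{coefficients}, \code{screen_alpha},
#'   \code{retain_alpha}.
#' @export
stepwise_select <- function(x, clinical, screen_alpha = 0.005,
                            retain_alpha = 0.1,
                            screen_family = c("cox", "logistic"),
                            final_family = c("logistic", "cox")) {
  stopifnot(inherits(x, "hir_expr"))
  screen_family <- match.arg(screen_family)
  final_family <- match.arg(final_family)
  df <- as.data.frame(clinical)
  if (sum(df$event) < 1) stop("need at least one event", call. = FALSE)
  v <- t(x$values)  # samples x genes
  stopifnot(nrow(v) == nrow(df))

  screen_p <- vapply(seq_len(ncol(v)), function(j) {
    g <- v[, j]
    if (stats::sd(g) == 0) return(1)
    if (screen_family == "cox") {
      f <- survival::coxph(survival::Surv(df$time_months, df$event) ~ g)
      summary(f)$coefficients[1, "Pr(>|z|)"]
    } else {
      f <- stats::glm(df$event ~ g, family = stats::binomial())
      summary(f)$coefficients[2, "Pr(>|z|)"]
    }
  }, 1)
  screened <- feature_ids(x)[screen_p < screen_alpha]
  if (!length(screened)) {
    warning("no genes pass the univariate screen")
    return(structure(list(screened_features = character(0),
                          selected_features = character(0),
                          coefficients = numeric(0),
                          screen_alpha = screen_alpha,
                          retain_alpha = retain_alpha),
                     class = "hir_stepwise"))
  }

  current <- sort(screened)
  repeat {
    dat <- data.frame(v[, current, drop = FALSE])
    names(dat) <- current
    if (final_family == "logistic") {
      dat$.y <- df$event
      fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
      co <- summary(fit)$coefficients
      co <- co[setdiff(rownames(co), "(Intercept)"), , drop = FALSE]
      pcol <- "Pr(>|z|)"
    } else {
      fit <- survival::coxph(
        survival::Surv(df$time_months, df$event) ~ ., data = dat)
      co <- summary(fit)$coefficients
      pcol <- "Pr(>|z|)"
    }
    alias <- setdiff(current, rownames(co))
    alias <- c(alias, rownames(co)[is.na(co[, pcol])])
    if (length(alias)) {
      warning("dropping collinear gene(s): ", paste(alias, collapse = ", "))
      current <- setdiff(current, alias)
      if (!length(current)) break
      next
    }
    pv <- co[, pcol]
    if (all(pv < retain_alpha)) break
    worst <- names(pv)[order(-pv, names(pv))][1L]
    current <- setdiff(current, worst)
    if (!length(current)) break
  }
  coefs <- if (length(current)) {
    stats::setNames(co[current, 1], current)
  } else numeric(0)
  structure(list(screened_features = screened,
                 selected_features = current,
                 coefficients = coefs,
                 screen_alpha = screen_alpha,
                 retain_alpha = retain_alpha),
            class = "hir_stepwise")
}
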