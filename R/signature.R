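#' Signature container
#'
#' An ordered feature set with per-feature weights (training
#' t-statistics) and derivation provenance. Weights are carried at the
#' feature (probe) level with gene-symbol annotation, so a signature can
#' hold more probes than unique genes.
#'
#' @param features data.frame with columns \code{feature_id},
#'   \code{gene_symbol}, \code{weight}.
#' @param alpha per-dataset significance threshold used at derivation.
#' @param provenance free-form list (dataset names, per-dataset
#'   significant counts, seeds).
#' @return object of class \code{hir_signature}.
#' @export
hir_signature <- function(features, alpha = 0.005, provenance = list()) {
  req <- c("feature_id", "gene_symbol", "weight")
  if (!all(req %in% names(features)))
    stop("features needs columns ", paste(req, collapse = ", "), call. = FALSE)
  structure(list(features = features[req], alpha = alpha,
                 provenance = provenance), class = "hir_signature")
}

#' @export
print.hir_signature <- function(x, ...) {
  cat(sprintf("<hir_signature> %d features / %d unique genes (alpha=%g)\n",
              nrow(x$features), length(unique(x$features$gene_symbol)),
              x$alpha))
  invisible(x)
}

#' @rdname hir_signature
#' @param x an \code{hir_signature}.
#' @return \code{signature_features}: the features data.frame.
#' @export
signature_features <- function(x) {
  stopifnot(inherits(x, "hir_signature"))
  x$features
}

#' Save / load a signature as JSON
#' @param x an \code{hir_signature}; \code{path} a file path.
#' @param path file path.
#' @export
write_signature <- function(x, path) {
  jsonlite::write_json(list(features = x$features, alpha = x$alpha,
                            provenance = x$provenance),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hir_signature(as.data.frame(obj$features), alpha = obj$alpha,
                provenance = as.list(obj$provenance))
}

#' Fit the inverse-gamma variance prior by maximum likelihood
#'
#' Assumes per-gene precisions \eqn{1/\sigma^2_g \sim \Gamma(a,
#' \mathrm{scale}\,b)}. The observed residual variances are then
#' marginally scaled F: \eqn{s^2_g \sim F(m, 2a) / (ab)}, and (a, b) are
#' obtained by maximizing the corresponding likelihood over the gene
#' ensemble.
#'
#' @param residual_variances positive per-gene residual variances.
#' @param df_per_gene residual degrees of freedom m (scalar or per-gene).
#' @return list with \code{a}, \code{b}, \code{converged}, and
#'   \code{degenerate} (TRUE when the variances are essentially constant
#'   and the prior weight saturates).
#' @export
fit_variance_prior <- function(residual_variances, df_per_gene) {
  s2 <- as.numeric(residual_variances)
  if (any(s2 <= 0)) stop("zero or negative variances", call. = FALSE)
  if (length(s2) < 50)
    warning("fewer than 50 genes; variance-prior fit may be unstable")
  m <- rep_len(as.numeric(df_per_gene), length(s2))
  # s2 ~ F(m, 2a)/(a b): log f(s2) = log df(s2 * a * b; m, 2a) + log(a b)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    ll <- stats::df(s2 * a * b, m, 2 * a, log = TRUE) + log(a * b)
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }
  init <- c(log(2), log(1 / (2 * stats::median(s2))))
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  a <- exp(fit$par[1]); b <- exp(fit$par[2])
  degenerate <- a > 1e3 || stats::sd(s2) / stats::median(s2) < 1e-8
  if (degenerate) a <- min(a, 1e6)
  list(a = a, b = b, converged = fit$convergence == 0,
       degenerate = degenerate)
}

rvt_core <- function(mean_diff, s2, m, cc, a, b) {
  shrunk <- (m * s2 + 2 / b) / (m + 2 * a)
  tt <- mean_diff / sqrt(shrunk * cc)
  df <- m + 2 * a
  p <- 2 * stats::pt(-abs(tt), df = df)
  data.frame(mean_diff = mean_diff, t_stat = tt, p_value = p,
             df = df, shrunken_variance = shrunk)
}

# Normalizes groups/design input into diff matrix (paired) or split
# (unpaired); shared by the t-test and the permutation test.
rvt_prepare <- function(x, groups) {
  stopifnot(inherits(x, "hir_expr"))
  v <- x$values
  if (inherits(groups, "hir_paired_design")) {
    pre <- match(groups$pre, colnames(v))
    post <- match(groups$post, colnames(v))
    if (anyNA(pre) || anyNA(post))
      stop("design refers to samples absent from the matrix", call. = FALSE)
    if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
    list(paired = TRUE, D = v[, post, drop = FALSE] - v[, pre, drop = FALSE])
  } else {
    g <- as.factor(groups)
    if (nlevels(g) != 2)
      stop("groups must have exactly two levels", call. = FALSE)
    if (any(table(g) < 2))
      stop("each class needs at least 2 samples", call. = FALSE)
    list(paired = FALSE, v = v, idx2 = which(g == levels(g)[2L]),
         n = ncol(v))
  }
}

rvt_stats <- function(prep, subset2 = NULL, signs = NULL) {
  if (prep$paired) {
    D <- prep$D
    J <- ncol(D)
    s <- signs %||% rep(1, J)
    md <- as.numeric(D %*% s) / J
    ss <- rowSums(D^2)
    s2 <- (ss - J * md^2) / (J - 1)
    list(mean_diff = md, s2 = pmax(s2, 0), m = J - 1, cc = 1 / J)
  } else {
    v <- prep$v
    i2 <- subset2 %||% prep$idx2
    i1 <- setdiff(seq_len(prep$n), i2)
    n1 <- length(i1); n2 <- length(i2)
    m1 <- rowMeans(v[, i1, drop = FALSE])
    m2 <- rowMeans(v[, i2, drop = FALSE])
    ss1 <- rowSums((v[, i1, drop = FALSE] - m1)^2)
    ss2 <- rowSums((v[, i2, drop = FALSE] - m2)^2)
    list(mean_diff = m2 - m1, s2 = (ss1 + ss2) / (n1 + n2 - 2),
         m = n1 + n2 - 2, cc = 1 / n1 + 1 / n2)
  }
}

#' Random-variance t-test
#'
#' Gene-wise t-test with variances shrunk toward an inverse-gamma prior
#' fitted across all genes. The shrunken variance is
#' \eqn{\tilde\sigma^2 = (m s^2 + 2/b)/(m + 2a)} and the statistic is
#' referred to a t distribution with \eqn{m + 2a} degrees of freedom, so
#' the ensemble prior effectively contributes 2a extra degrees of
#' freedom per gene. As \eqn{a \to 0, b \to \infty} the ordinary Student
#' t-test is recovered.
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param groups either a two-level factor over samples (unpaired; the
#'   difference is second level minus first) or a
#'   \code{\link{paired_design}} (test on post minus pre differences).
#' @param prior list with \code{a}, \code{b}; if NULL it is fitted from
#'   the data with \code{\link{fit_variance_prior}}.
#' @return data.frame, one row per feature: \code{feature_id},
#'   \code{gene_symbol}, \code{mean_diff}, \code{t_stat}, \code{p_value},
#'   \code{df}, \code{shrunken_variance}.
#' @export
random_variance_ttest <- function(x, groups, prior = NULL) {
  prep <- rvt_prepare(x, groups)
  st <- rvt_stats(prep)
  if (is.null(prior)) prior <- fit_variance_prior(st$s2, st$m)
  res <- rvt_core(st$mean_diff, st$s2, st$m, st$cc, prior$a, prior$b)
  cbind(data.frame(feature_id = feature_ids(x),
                   gene_symbol = x$gene_symbols), res)
}

#' Derive a signature by intersecting per-dataset differential expression
#'
#' Runs the random-variance t-test in each paired injury dataset, keeps
#' genes significant at \code{alpha} in every dataset, and weights the
#' surviving features with t-statistics from a pooled paired test across
#' all datasets (all pairs stacked). An empty intersection yields a valid
#' empty signature with a warning.
#'
#' @param datasets list of lists with elements \code{expression} and
#'   \code{design} (as produced by \code{\link{generate_paired_datasets}}).
#' @param alpha per-dataset significance threshold (default 0.005).
#' @param weight_source \code{"pooled"} (default) or the index of a
#'   reference dataset whose t-statistics become the weights.
#' @return an \code{\link{hir_signature}}.
#' @export
derive_signature <- function(datasets, alpha = 0.005,
                             weight_source = "pooled") {
  stopifnot(length(datasets) >= 1)
  tests <- lapply(datasets, function(d)
    random_variance_ttest(d$expression, d$design))
  sig_sets <- lapply(tests, function(tb) tb$feature_id[tb$p_value < alpha])
  keep <- Reduce(intersect, sig_sets)
  if (identical(weight_source, "pooled")) {
    Ds <- lapply(datasets, function(d)
      rvt_prepare(d$expression, d$design)$D)
    D <- do.call(cbind, Ds)
    x0 <- datasets[[1L]]$expression
    st <- rvt_stats(list(paired = TRUE, D = D))
    prior <- fit_variance_prior(st$s2, st$m)
    core <- rvt_core(st$mean_diff, st$s2, st$m, st$cc, prior$a, prior$b)
    wtab <- cbind(data.frame(feature_id = feature_ids(x0),
                             gene_symbol = x0$gene_symbols), core)
  } else {
    wtab <- tests[[weight_source]]
  }
  if (!length(keep)) {
    warning("empty intersection: signature has no features")
    feats <- data.frame(feature_id = character(0),
                        gene_symbol = character(0), weight = numeric(0))
  } else {
    i <- match(keep, wtab$feature_id)
    feats <- data.frame(feature_id = keep,
                        gene_symbol = wtab$gene_symbol[i],
                        weight = wtab$t_stat[i])
    feats <- feats[order(-abs(feats$weight)), ]
    rownames(feats) <- NULL
  }
  hir_signature(feats, alpha = alpha,
                provenance = list(
                  n_datasets = length(datasets),
                  per_dataset_significant = vapply(sig_sets, length, 1L),
                  weight_source = weight_source))
}

#' Permutation global test for differential expression
#'
#' Tests whether expression differs between the two classes at all by
#' permuting class labels (unpaired) or flipping pair signs (paired),
#' recomputing gene-wise p-values for each permutation, and counting
#' genes significant at \code{alpha}. The global p-value is the
#' proportion of permutations with at least as many significant genes as
#' observed; sampled permutations use the add-one estimator
#' \eqn{(1 + \#\{c_{perm} \ge c_{obs}\})/(1 + B)} so it cannot be zero.
#' When the number of distinct permutations does not exceed
#' \code{n_perm}, all of them are enumerated instead and the result is
#' flagged exhaustive. Monte Carlo sampling skips the trivial
#' permutations (the observed labeling and its mirror; all-plus/all-minus
#' sign vectors), which reproduce the observed statistics exactly and
#' would otherwise put a hard floor of 2/(B+1) under the p-value;
#' exhaustive enumeration keeps them.
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param groups two-level factor or \code{\link{paired_design}}.
#' @param alpha gene-level threshold (default 0.005).
#' @param n_perm permutations requested (default 1000).
#' @param seed RNG seed for sampled permutations.
#' @return list: \code{global_p}, \code{observed_count},
#'   \code{perm_counts}, \code{exhaustive}, \code{n_perm_used}.
#' @export
global_permutation_test <- function(x, groups, alpha = 0.005,
                                    n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 1)
  prep <- rvt_prepare(x, groups)
  st <- rvt_stats(prep)
  prior <- fit_variance_prior(st$s2, st$m)
  count_sig <- function(st) {
    res <- rvt_core(st$mean_diff, st$s2, st$m, st$cc, prior$a, prior$b)
    sum(res$p_value < alpha)
  }
  obs <- count_sig(st)

  if (prep$paired) {
    J <- ncol(prep$D)
    n_distinct <- 2^J
    exhaustive <- n_distinct <= n_perm
    if (exhaustive) {
      grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), J)))
      counts <- apply(grid, 1L, function(s)
        count_sig(rvt_stats(prep, signs = s)))
    } else {
      counts <- with_substream(seed, 0L, expr =
        vapply(seq_len(n_perm), function(i) {
          repeat {
            s <- sample(c(-1, 1), J, TRUE)
            # +/- identity reproduce |t| exactly and carry no information
            if (abs(sum(s)) != J) break
          }
          count_sig(rvt_stats(prep, signs = s))
        }, 1))
    }
  } else {
    n2 <- length(prep$idx2)
    n_distinct <- choose(prep$n, n2)
    exhaustive <- n_distinct <= n_perm
    if (exhaustive) {
      combs <- utils::combn(prep$n, n2)
      counts <- apply(combs, 2L, function(i2)
        count_sig(rvt_stats(prep, subset2 = i2)))
    } else {
      obs_set <- sort(prep$idx2)
      comp_set <- sort(setdiff(seq_len(prep$n), prep$idx2))
      counts <- with_substream(seed, 0L, expr =
        vapply(seq_len(n_perm), function(i) {
          repeat {
            i2 <- sort(sample(prep$n, n2))
            # skip the observed split and its mirror (exact-tie copies)
            if (!identical(i2, obs_set) && !identical(i2, comp_set)) break
          }
          count_sig(rvt_stats(prep, subset2 = i2))
        }, 1))
    }
  }
  gp <- if (exhaustive) mean(counts >= obs)
        else (1 + sum(counts >= obs)) / (1 + length(counts))
  list(global_p = gp, observed_count = obs, perm_counts = counts,
       exhaustive = exhaustive, n_perm_used = length(counts))
}
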