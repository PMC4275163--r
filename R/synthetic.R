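#' Configuration for the synthetic-data generator
#'
#' Builds and validates the parameter set that drives both halves of the
#' generator: (i) paired pre/post-injury liver datasets used to derive an
#' injury/regeneration signature, and (ii) HCC cohorts with a latent
#' HIR/QT class in adjacent tissue, a tumor-derived risk score, and
#' recurrence times from a piecewise-exponential hazard (early window
#' driven by the tumor score, late window by the HIR class).
#'
#' Gene-level variances follow an inverse-gamma model: the precision
#' \eqn{1/\sigma^2_g \sim \mathrm{Gamma}(a, \mathrm{scale}=b)}, the same
#' family assumed by the random-variance t-test, so the generator and the
#' test share a stated world.
#'
#' @param n_genes number of gene features.
#' @param n_signature number of planted injury-responsive features.
#' @param n_datasets number of paired injury datasets.
#' @param pairs_per_dataset biopsy pairs per dataset.
#' @param prior_shape_a,prior_rate_b shape and scale of the Gamma precision
#'   prior (mean precision \code{a*b}).
#' @param injury_effect log2 shift added to planted genes post vs pre.
#' @param pair_correlation within-pair correlation in [0,1) induced by an
#'   additive Gaussian pair intercept.
#' @param cohort_size patients per simulated HCC cohort.
#' @param prop_hir probability a patient carries the latent HIR class.
#' @param class_shift_d log2 shift of signature genes in HIR adjacent tissue.
#' @param n_tumor_score_genes genes in the tumor matrix loaded on the
#'   tumor risk score.
#' @param early_hazard_base,late_hazard_base baseline hazards (events/month)
#'   before and after the changepoint.
#' @param cutoff_tau changepoint between early and late hazard (months).
#' @param beta_early log hazard ratio per unit tumor score, early window.
#' @param beta_late log hazard ratio HIR vs QT, late window.
#' @param censor_max censoring times are Uniform(0, censor_max) months.
#' @param seed integer master seed; identical seed + config gives
#'   bit-identical output.
#' @return object of class \code{hir_syn_config}.
#' @export
syn_config <- function(n_genes = 2000L, n_signature = 50L, n_datasets = 3L,
                       pairs_per_dataset = 10L,
                       prior_shape_a = 3, prior_rate_b = 8,
                       injury_effect = 1.5, pair_correlation = 0.5,
                       cohort_size = 400L, prop_hir = 0.35,
                       class_shift_d = 1.0, n_tumor_score_genes = 65L,
                       early_hazard_base = 0.02, late_hazard_base = 0.01,
                       cutoff_tau = 24, beta_early = log(1.8),
                       beta_late = log(2.2), censor_max = 120,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_signature = as.integer(n_signature),
              n_datasets = as.integer(n_datasets),
              pairs_per_dataset = as.integer(pairs_per_dataset),
              prior_shape_a = prior_shape_a, prior_rate_b = prior_rate_b,
              injury_effect = injury_effect, pair_correlation = pair_correlation,
              cohort_size = as.integer(cohort_size), prop_hir = prop_hir,
              class_shift_d = class_shift_d,
              n_tumor_score_genes = as.integer(n_tumor_score_genes),
              early_hazard_base = early_hazard_base,
              late_hazard_base = late_hazard_base,
              cutoff_tau = cutoff_tau, beta_early = beta_early,
              beta_late = beta_late, censor_max = censor_max,
              seed = as.integer(seed))
  validate_syn_config(cfg)
  structure(cfg, class = "hir_syn_config")
}

validate_syn_config <- function(cfg) {
  chk_count <- function(f, min = 1L) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < min)
      stop_param(f, sprintf("must be a single integer >= %d", min))
  }
  chk_pos <- function(f) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0)
      stop_param(f, "must be a single positive number")
  }
  for (f in c("n_genes", "n_signature", "n_datasets", "pairs_per_dataset",
              "cohort_size")) chk_count(f)
  chk_count("n_tumor_score_genes", 0L)
  for (f in c("prior_shape_a", "prior_rate_b", "early_hazard_base",
              "late_hazard_base", "cutoff_tau", "censor_max")) chk_pos(f)
  if (cfg$n_signature > cfg$n_genes)
    stop_param("n_signature", "must not exceed n_genes")
  if (cfg$n_tumor_score_genes > cfg$n_genes)
    stop_param("n_tumor_score_genes", "must not exceed n_genes")
  if (cfg$prop_hir < 0 || cfg$prop_hir > 1)
    stop_param("prop_hir", "must lie in [0, 1]")
  if (cfg$pair_correlation < 0 || cfg$pair_correlation >= 1)
    stop_param("pair_correlation", "must lie in [0, 1)")
  invisible(cfg)
}

# Gene-level parameters are drawn on their own substream so every dataset
# and every cohort generated from the same config sees the same genes.
syn_gene_params <- function(cfg) {
  with_substream(cfg$seed, 1L, expr = {
    feature_ids <- sprintf("FT%05d", seq_len(cfg$n_genes))
    gene_symbols <- sprintf("GENE%05d", seq_len(cfg$n_genes))
    mu <- stats::rnorm(cfg$n_genes, mean = 7, sd = 1)
    prec <- stats::rgamma(cfg$n_genes, shape = cfg$prior_shape_a,
                          scale = cfg$prior_rate_b)
    planted <- sort(sample.int(cfg$n_genes, cfg$n_signature))
    tumor_genes <- sort(sample.int(cfg$n_genes, cfg$n_tumor_score_genes))
    list(feature_ids = feature_ids, gene_symbols = gene_symbols,
         mu = mu, sigma = sqrt(1 / prec), planted = planted,
         tumor_genes = tumor_genes)
  })
}

#' Generate paired pre/post-injury expression datasets
#'
#' Simulates \code{n_datasets} paired designs (pre- and post-injury biopsy
#' per subject). For each gene, variance is drawn under the inverse-gamma
#' precision model; planted signature genes gain \code{injury_effect} log2
#' units post-injury; a per-pair Gaussian intercept induces the configured
#' within-pair correlation.
#'
#' @param cfg a \code{\link{syn_config}} object.
#' @return list with \code{datasets} (each a list of \code{expression}
#'   [an \code{\link{expression_matrix}}] and \code{design} [a
#'   \code{\link{paired_design}}]) and \code{truth}
#'   (planted feature IDs and generating parameters).
#' @export
generate_paired_datasets <- function(cfg) {
  stopifnot(inherits(cfg, "hir_syn_config"))
  gp <- syn_gene_params(cfg)
  is_planted <- seq_len(cfg$n_genes) %in% gp$planted
  delta <- ifelse(is_planted, cfg$injury_effect, 0)
  rho <- cfg$pair_correlation
  sd_pair <- gp$sigma * sqrt(rho / (1 - rho))

  datasets <- vector("list", cfg$n_datasets)
  for (k in seq_len(cfg$n_datasets)) {
    npair <- cfg$pairs_per_dataset
    pre <- post <- matrix(0, cfg$n_genes, npair)
    for (j in seq_len(npair)) {
      draws <- with_substream(cfg$seed, 2L, k, j, expr = {
        b <- stats::rnorm(cfg$n_genes, 0, sd_pair)
        e1 <- stats::rnorm(cfg$n_genes, 0, gp$sigma)
        e2 <- stats::rnorm(cfg$n_genes, 0, gp$sigma)
        list(b = b, e1 = e1, e2 = e2)
      })
      pre[, j] <- gp$mu + draws$b + draws$e1
      post[, j] <- gp$mu + draws$b + delta + draws$e2
    }
    samp <- c(sprintf("DS%d_P%02d_pre", k, seq_len(npair)),
              sprintf("DS%d_P%02d_post", k, seq_len(npair)))
    em <- expression_matrix(cbind(pre, post), feature_ids = gp$feature_ids,
                            gene_symbols = gp$gene_symbols, sample_ids = samp)
    des <- paired_design(name = sprintf("injury_ds%d", k),
                         pre = samp[seq_len(npair)],
                         post = samp[npair + seq_len(npair)])
    datasets[[k]] <- list(expression = em, design = des)
  }
  truth <- list(planted_signature = gp$feature_ids[gp$planted],
                injury_effect = cfg$injury_effect,
                sigma = stats::setNames(gp$sigma, gp$feature_ids))
  list(datasets = datasets, truth = truth)
}

#' Paired before/after design
#'
#' Records which samples form pre/post pairs within one injury dataset.
#'
#' @param name dataset label.
#' @param pre,post equal-length character vectors of sample IDs; element i
#'   of each forms pair i.
#' @return object of class \code{hir_paired_design}.
#' @export
paired_design <- function(name, pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length", call. = FALSE)
  structure(list(name = name, pre = as.character(pre),
                 post = as.character(post)), class = "hir_paired_design")
}

#' Generate a synthetic HCC cohort with known ground truth
#'
#' Each patient carries a latent class (HIR with probability
#' \code{prop_hir}, else QT) and a standard-normal tumor risk score.
#' Adjacent non-tumor tissue shifts the signature genes by
#' \code{class_shift_d} in HIR patients; the tumor matrix loads the tumor
#' score onto \code{n_tumor_score_genes} genes. Recurrence time follows a
#' piecewise-exponential hazard
#' \deqn{h(t) = h_{E0} e^{\beta_E r_i} \; (t < \tau), \qquad
#'       h(t) = h_{L0} e^{\beta_L z_i} \; (t \ge \tau)}
#' with independent Uniform(0, censor_max) censoring. This encodes the
#' dual-mechanism recurrence structure: early relapse driven by the
#' tumor-derived score, late relapse by the injured-liver field effect.
#'
#' @param cfg a \code{\link{syn_config}} object.
#' @param signature optional \code{hir_signature}; its features must exist
#'   in the generated gene universe. Defaults to the planted set.
#' @param cohort_id integer tag so multiple cohorts from one seed differ.
#' @return list with \code{adjacent} and \code{tumor} expression matrices,
#'   \code{clinical} (a clinical table, see \code{\link{clinical_table}}),
#'   and \code{truth} (per-patient class and tumor score, true hazard
#'   ratios, planted features).
#' @export
generate_cohort <- function(cfg, signature = NULL, cohort_id = 1L) {
  stopifnot(inherits(cfg, "hir_syn_config"))
  gp <- syn_gene_params(cfg)
  if (!is.null(signature)) {
    feats <- signature_features(signature)$feature_id
    missing <- setdiff(feats, gp$feature_ids)
    if (length(missing))
      stop("signature features absent from generated genes: ",
           paste(missing, collapse = ", "), call. = FALSE)
    shifted <- match(feats, gp$feature_ids)
  } else {
    shifted <- gp$planted
  }
  n <- cfg$cohort_size
  g <- cfg$n_genes

  adj <- tum <- matrix(0, g, n)
  time <- ev <- numeric(n)
  z <- integer(n); r <- numeric(n)
  load <- numeric(g); load[gp$tumor_genes] <- 0.8
  shift <- numeric(g); shift[shifted] <- cfg$class_shift_d
  covar <- vector("list", n)
  # every patient owns a substream so growing the cohort leaves earlier
  # patients' draws untouched
  for (i in seq_len(n)) {
    d <- with_substream(cfg$seed, 3L, cohort_id, i, expr = {
      list(z = stats::rbinom(1L, 1L, cfg$prop_hir),
           r = stats::rnorm(1L),
           ea = stats::rnorm(g, 0, gp$sigma),
           et = stats::rnorm(g, 0, gp$sigma),
           E = stats::rexp(1), U = stats::runif(1),
           cv = c(stats::rbinom(7L, 1L,
                                c(0.8, 0.3, 0.75, 0.6, 0.3, 0.2, 0.35)),
                  stats::rnorm(1L, 55, 10),
                  sample.int(4L, 1L, prob = c(0.1, 0.6, 0.2, 0.1))))
    })
    z[i] <- d$z; r[i] <- d$r
    adj[, i] <- gp$mu + shift * z[i] + d$ea
    tum[, i] <- gp$mu + load * r[i] + d$et
    hE <- cfg$early_hazard_base * exp(cfg$beta_early * r[i])
    hL <- cfg$late_hazard_base * exp(cfg$beta_late * z[i])
    tt <- if (d$E < hE * cfg$cutoff_tau) d$E / hE
          else cfg$cutoff_tau + (d$E - hE * cfg$cutoff_tau) / hL
    cc <- d$U * cfg$censor_max
    time[i] <- min(tt, cc)
    ev[i] <- as.integer(tt <= cc)
    covar[[i]] <- data.frame(
      sex = d$cv[1], age = round(d$cv[8]), afp_gt_300 = d$cv[2],
      hbv = d$cv[3], cirrhosis = d$cv[4], tumor_gt_5cm = d$cv[5],
      multinodular = d$cv[6], vascular_invasion = d$cv[7],
      bclc = c("0", "A", "B", "C")[d$cv[9]])
  }
  pid <- sprintf("C%d_PT%04d", cohort_id, seq_len(n))
  covar <- do.call(rbind, covar)
  clin <- clinical_table(cbind(data.frame(patient_id = pid,
                                          time_months = time,
                                          event = ev), covar))
  mk <- function(v, tag) expression_matrix(
    v, feature_ids = gp$feature_ids, gene_symbols = gp$gene_symbols,
    sample_ids = pid)
  list(adjacent = mk(adj), tumor = mk(tum), clinical = clin,
       truth = list(planted_signature = gp$feature_ids[gp$planted],
                    per_patient_class = ifelse(z == 1, "HIR", "QT"),
                    per_patient_tumor_score = r,
                    true_late_hr = exp(cfg$beta_late),
                    true_early_hr_per_unit = exp(cfg$beta_early)))
}

#' Write a generated scenario to disk
#'
#' Expression as TSV (feature_id, gene_symbol, then one column per
#' sample), clinical as TSV, config and ground truth as JSON. All files
#' carry a provenance comment header.
#'
#' @param cfg a \code{\link{syn_config}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
write_scenario <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- generate_paired_datasets(cfg)
  co <- generate_cohort(cfg)
  paths <- character(0)
  for (k in seq_along(pd$datasets)) {
    p <- file.path(dir, sprintf("injury_ds%d.tsv", k))
    write_expression(pd$datasets[[k]]$expression, p, seed = cfg$seed)
    dput_design <- file.path(dir, sprintf("injury_ds%d_pairs.tsv", k))
    utils::write.table(
      data.frame(pre = pd$datasets[[k]]$design$pre,
                 post = pd$datasets[[k]]$design$post),
      dput_design, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p, dput_design)
  }
  pa <- file.path(dir, "cohort_adjacent.tsv")
  pt <- file.path(dir, "cohort_tumor.tsv")
  pc <- file.path(dir, "cohort_clinical.tsv")
  write_expression(co$adjacent, pa, seed = cfg$seed)
  write_expression(co$tumor, pt, seed = cfg$seed)
  write_clinical(co$clinical, pc, seed = cfg$seed)
  pj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(c(co$truth,
                         list(planted_paired = pd$truth$planted_signature)),
                       pj, auto_unbox = TRUE, digits = NA)
  pg <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), pg, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pa, pt, pc, pj, pg))
}
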