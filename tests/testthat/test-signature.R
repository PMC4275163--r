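test_that("variance-prior ML recovers generating (a, b) within 10%", {
  set.seed(1)
  m <- 18
  tau <- rgamma(10000, shape = 2, scale = 0.5)
  s2 <- (1 / tau) * rchisq(10000, m) / m
  fit <- fit_variance_prior(s2, m)
  expect_lt(abs(fit$a - 2) / 2, 0.1)
  expect_lt(abs(fit$b - 0.5) / 0.5, 0.1)
  expect_false(fit$degenerate)
})

test_that("variance-prior degenerate and tiny inputs behave per contract", {
  fit <- suppressWarnings(fit_variance_prior(rep(1, 100), 10))
  expect_true(fit$degenerate)
  expect_warning(fit_variance_prior(c(0.5, 0.7), 10), "fewer than 50")
  expect_error(fit_variance_prior(c(1, 0), 10), "zero or negative")
})

test_that("identical groups give t = 0, p = 1", {
  v <- matrix(rnorm(40), 4, 10)
  em <- toy_expr(cbind(v, v))
  des <- paired_design("dup", pre = sprintf("s%02d", 1:10),
                       post = sprintf("s%02d", 11:20))
  tb <- random_variance_ttest(em, des, prior = list(a = 2, b = 1))
  expect_equal(tb$t_stat, rep(0, 4))
  expect_equal(tb$p_value, rep(1, 4))
})

test_that("prior-free limit reproduces the ordinary Student t-test", {
  set.seed(8)
  em <- toy_expr(matrix(rnorm(12), 2, 6))
  g <- rep(c("A", "B"), each = 3)
  tb <- random_variance_ttest(em, g, prior = list(a = 1e-12, b = 1e12))
  oracle <- apply(em$values, 1, function(r)
    t.test(r[4:6], r[1:3], var.equal = TRUE)$statistic)
  expect_equal(tb$t_stat, unname(oracle), tolerance = 1e-8)
  # monotone in |mean_diff| at fixed variance
  tb2 <- hirrecur:::rvt_core(c(0.1, 0.5, 1, 2), rep(1, 4), 10, 0.2, 2, 1)
  expect_true(all(diff(tb2$t_stat) > 0))
})

test_that("signature derivation recovers the planted set and obeys laws", {
  cfg <- desk_config()
  pd <- generate_paired_datasets(cfg)
  sig <- derive_signature(pd$datasets)
  feats <- signature_features(sig)$feature_id
  hits <- intersect(feats, pd$truth$planted_signature)
  expect_gte(length(hits), 0.9 * cfg$n_signature)
  expect_lte(length(setdiff(feats, pd$truth$planted_signature)), 5)
  # invariant under dataset ordering
  sig_rev <- derive_signature(rev(pd$datasets))
  expect_setequal(feats, signature_features(sig_rev)$feature_id)
  # alpha = 1 keeps everything
  sig_all <- derive_signature(pd$datasets, alpha = 1)
  expect_identical(nrow(signature_features(sig_all)), cfg$n_genes)
  # a dataset with no signal empties the intersection
  null_cfg <- desk_config(injury_effect = 0)
  null_pd <- generate_paired_datasets(null_cfg)
  mixed <- c(pd$datasets[1:2], null_pd$datasets[3])
  expect_warning(sig0 <- derive_signature(mixed, alpha = 1e-10),
                 "empty intersection")
  expect_identical(nrow(signature_features(sig0)), 0L)
})

test_that("signature JSON round-trips", {
  cfg <- desk_config()
  sig <- derive_signature(generate_paired_datasets(cfg)$datasets)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(signature_features(back), signature_features(sig),
               tolerance = 1e-12)
  expect_equal(back$alpha, sig$alpha)
})

test_that("exhaustive 2v2 permutation test matches brute force", {
  set.seed(21)
  em <- toy_expr(matrix(rnorm(80, sd = 0.5) +
                          c(rep(2, 10), rep(0, 10)) %o% c(0, 0, 1, 1),
                        20, 4))
  g <- c("A", "A", "B", "B")
  res <- suppressWarnings(
    global_permutation_test(em, g, alpha = 0.05, n_perm = 1000))
  expect_true(res$exhaustive)
  expect_identical(res$n_perm_used, 6L)
  # independent brute-force oracle: plain per-gene recomputation with the
  # same fixed prior over all 6 assignments of samples to class B
  st <- hirrecur:::rvt_stats(hirrecur:::rvt_prepare(em, g))
  prior <- suppressWarnings(fit_variance_prior(st$s2, st$m))
  count_for <- function(idx2) {
    v <- em$values
    n_sig <- 0
    for (r in seq_len(nrow(v))) {
      x2 <- v[r, idx2]; x1 <- v[r, -idx2]
      s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 2
      shrunk <- (2 * s2 + 2 / prior$b) / (2 + 2 * prior$a)
      tt <- (mean(x2) - mean(x1)) / sqrt(shrunk * 1)
      if (2 * pt(-abs(tt), df = 2 + 2 * prior$a) < 0.05) n_sig <- n_sig + 1
    }
    n_sig
  }
  combs <- combn(4, 2)
  oracle_counts <- apply(combs, 2, count_for)
  obs <- count_for(3:4)
  expect_equal(sort(res$perm_counts), sort(oracle_counts),
               ignore_attr = TRUE)
  expect_equal(res$global_p, mean(oracle_counts >= obs))
})

test_that("global test boundary cases", {
  # nothing significant => p = 1
  set.seed(31)
  em <- toy_expr(matrix(rnorm(400), 20, 20))
  des <- paired_design("n", sprintf("s%02d", 1:10), sprintf("s%02d", 11:20))
  res <- suppressWarnings(
    global_permutation_test(em, des, alpha = 1e-12, n_perm = 50))
  expect_identical(res$observed_count, 0L)
  expect_equal(res$global_p, 1)
  # strong planted signal with sampled permutations: the add-one estimator
  # is bounded below by 1/(B+1); single-pair sign flips retain most of a
  # strong signal, so ties above that floor are legitimate, but the global
  # p must still be decisively small
  cfg <- desk_config()
  pd <- generate_paired_datasets(cfg)
  res <- global_permutation_test(pd$datasets[[1]]$expression,
                                 pd$datasets[[1]]$design,
                                 n_perm = 199, seed = 2)
  expect_false(res$exhaustive)
  expect_gte(res$global_p, 1 / 200)
  expect_lte(res$global_p, 0.05)
})
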