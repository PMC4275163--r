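test_that("NSC at delta 0 equals the brute-force nearest-centroid oracle", {
  set.seed(12)
  v <- matrix(rnorm(30), 5, 6)
  v[1:2, 4:6] <- v[1:2, 4:6] + 2
  em <- toy_expr(v)
  labels <- rep(c("QT", "HIR"), each = 3)
  fit <- nsc_fit(em, labels, delta_grid = c(0, 0.5, 1, 2, 5), cv_folds = 3)
  pred <- predict(fit, em, delta = 0)
  # brute force: standardized squared distance to each unshrunken class
  # centroid, explicit loops, same pooled sd + s0 definition
  lv <- sort(unique(labels))
  cent <- sapply(lv, function(l) rowMeans(v[, labels == l]))
  ss <- rowSums((v[, labels == lv[1]] - cent[, lv[1]])^2) +
    rowSums((v[, labels == lv[2]] - cent[, lv[2]])^2)
  s <- sqrt(ss / (6 - 2)); s0 <- median(s)
  oracle <- character(6)
  for (i in 1:6) {
    d <- sapply(lv, function(l)
      sum(((v[, i] - cent[, l]) / (s + s0))^2) - 2 * log(0.5))
    oracle[i] <- lv[which.min(d)]
  }
  expect_identical(pred, oracle)
})

test_that("NSC shrinkage laws: monotone survival, prior fallback", {
  tc <- two_class_expr(n_per_class = 10, n_genes = 30, shift = 2.5,
                       n_informative = 8, seed = 14)
  fit <- nsc_fit(tc$expr, tc$labels, cv_folds = 5)
  expect_identical(fit$n_surviving[1], 30L)  # delta = 0 keeps all
  expect_true(all(diff(fit$n_surviving) <= 0))
  expect_error(nsc_fit(tc$expr, tc$labels, delta_grid = c(-1, 0)), "delta")
  # beyond max |d| nothing survives and prediction falls back to priors
  big <- max(abs(fit$stats$d)) + 1
  fit2 <- nsc_fit(tc$expr, tc$labels, delta_grid = c(0, big), cv_folds = 5)
  expect_identical(fit2$n_surviving[2], 0L)
  pred <- predict(fit2, tc$expr, delta = big)
  expect_identical(unique(pred), "HIR")  # ties broken by larger prior index
})

test_that("NSC finds a compact accurate model in a strong-signal regime", {
  cfg <- desk_config(cohort_size = 120L)
  pl <- hirrecur:::classify_pipeline(cfg)
  truth <- pl$cohort$truth$per_patient_class
  adj <- match_and_center(pl$cohort$adjacent, pl$signature)
  fit <- nsc_fit(adj, truth, cv_folds = 5, seed = 3)
  ok <- fit$n_surviving >= 10 & fit$n_surviving <= 20
  expect_true(any(ok))
  expect_lte(min(fit$cv_error[ok]), 0.10)
})

test_that("category-stratified panel selection is deterministic and exact", {
  feats <- data.frame(feature_id = sprintf("f%02d", 1:30),
                      gene_symbol = sprintf("g%02d", 1:30),
                      weight = rnorm(30))
  sig <- hir_signature(feats)
  cats <- setNames(rep(sprintf("cat%02d", 1:10), 3), feats$feature_id)
  sel1 <- select_by_category(sig, cats, seed = 5)
  sel2 <- select_by_category(sig, cats, seed = 5)
  expect_identical(as.character(sel1), as.character(sel2))
  expect_length(sel1, 20L)
  expect_true(all(table(attr(sel1, "selection")$category) == 2))
  # exactly 2 per category forces the unique selection
  cats2 <- setNames(rep(sprintf("cat%02d", 1:10), 2), feats$feature_id[1:20])
  sel3 <- select_by_category(hir_signature(feats[1:20, ]), cats2, seed = 1)
  expect_setequal(as.character(sel3), feats$feature_id[1:20])
  # too-small categories are named in the error
  cats3 <- setNames(c(rep("a", 2), rep("solo", 1), rep("b", 2)),
                    feats$feature_id[1:5])
  expect_error(select_by_category(hir_signature(feats[1:5, ]), cats3,
                                  n_categories = 3), "solo")
})

test_that("stepwise selection: null calibration and planted recovery", {
  # null: expected screened count ~ G * alpha
  screened <- vapply(1:10, function(r) {
    set.seed(600 + r)
    n <- 80; G <- 100
    em <- toy_expr(matrix(rnorm(G * n), G, n))
    tt <- rexp(n, 0.05); cen <- runif(n, 0, 40)
    clin <- clinical_table(data.frame(patient_id = 1:n,
                                      time_months = pmin(tt, cen),
                                      event = as.integer(tt <= cen)))
    sw <- suppressWarnings(stepwise_select(em, clin, screen_alpha = 0.05))
    length(sw$screened_features)
  }, 1)
  expect_lt(mean(screened), 3 * 100 * 0.05 + 1)
  # planted: 2 predictive genes among 50 nulls
  hits <- vapply(1:10, function(r) {
    set.seed(700 + r)
    n <- 300; G <- 52
    v <- matrix(rnorm(G * n), G, n)
    risk <- 0.8 * v[1, ] + 0.8 * v[2, ]
    tt <- rexp(n, 0.03 * exp(risk)); cen <- runif(n, 0, 60)
    em <- toy_expr(v)
    clin <- clinical_table(data.frame(patient_id = 1:n,
                                      time_months = pmin(tt, cen),
                                      event = as.integer(tt <= cen)))
    sw <- stepwise_select(em, clin)
    all(c("f01", "f02") %in% sw$selected_features)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("stepwise contracts: subset law, order invariance, collinearity", {
  set.seed(15)
  n <- 150; G <- 20
  v <- matrix(rnorm(G * n), G, n)
  risk <- v[1, ]
  tt <- rexp(n, 0.05 * exp(risk)); cen <- runif(n, 0, 40)
  clin <- clinical_table(data.frame(patient_id = 1:n,
                                    time_months = pmin(tt, cen),
                                    event = as.integer(tt <= cen)))
  em <- toy_expr(v)
  sw <- stepwise_select(em, clin, screen_alpha = 0.05)
  expect_true(all(sw$selected_features %in% sw$screened_features))
  # row order must not change the selected set
  perm <- sample(G)
  em2 <- expression_matrix(v[perm, ], rownames(em$values)[perm],
                           em$gene_symbols[perm], colnames(em$values))
  sw2 <- stepwise_select(em2, clin, screen_alpha = 0.05)
  expect_setequal(sw$selected_features, sw2$selected_features)
  # duplicated gene: run completes, one of the pair dropped
  v3 <- rbind(v[1, , drop = FALSE], v)
  em3 <- toy_expr(v3)
  expect_warning(sw3 <- stepwise_select(em3, clin, screen_alpha = 0.05),
                 "collinear")
  expect_false(all(c("f01", "f02") %in% sw3$selected_features))
  # empty screen yields an empty result with a warning (pure-noise genes)
  set.seed(16)
  em_null <- toy_expr(matrix(rnorm(10 * n), 10, n))
  expect_warning(sw4 <- stepwise_select(em_null, clin, screen_alpha = 1e-8),
                 "no genes pass")
  expect_length(sw4$selected_features, 0L)
})
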