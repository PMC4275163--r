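test_that("KM matches the hand product-limit oracle", {
  clin <- clinical_table(data.frame(patient_id = 1:6,
                                    time_months = c(1, 2, 3, 4, 5, 6),
                                    event = c(1, 0, 1, 1, 0, 1)))
  km <- km_estimate(clin)
  s3 <- km$curves$surv[km$curves$time == 3]
  expect_equal(s3, (5 / 6) * (3 / 4))
  # no events => survival identically 1
  none <- clinical_table(data.frame(patient_id = 1:4,
                                    time_months = 1:4, event = rep(0L, 4)))
  expect_true(all(km_estimate(none)$curves$surv == 1))
  # no censoring => 1 - ECDF
  all_ev <- clinical_table(data.frame(patient_id = 1:5,
                                      time_months = c(2, 4, 6, 8, 10),
                                      event = rep(1L, 5)))
  expect_equal(km_estimate(all_ev)$curves$surv, 1 - (1:5) / 5)
})

test_that("log-rank matches a hand-computed O-E event table", {
  # groups A: events at 1, 3; B: event at 2, censored at 4
  clin <- clinical_table(data.frame(patient_id = 1:4,
                                    time_months = c(1, 3, 2, 4),
                                    event = c(1, 1, 1, 0)))
  g <- c("A", "A", "B", "B")
  # t=1: risk 2A+2B, event A: E_A=0.5; t=2: risk 1A+2B, event B: E_A=1/3
  # t=3: risk 1A+1B, event A: E_A=0.5 ; O_A=2, E_A=4/3
  # V = sum of hypergeometric variances at each event time
  v1 <- (2 * 2 * 1 * 3) / (4^2 * 3)
  v2 <- (1 * 2 * 1 * 2) / (3^2 * 2)
  v3 <- (1 * 1 * 1 * 1) / (2^2 * 1)
  chi_hand <- (2 - 4 / 3)^2 / (v1 + v2 + v3)
  lr <- logrank_test(clin, g)
  expect_equal(lr$chi2, chi_hand, tolerance = 1e-9)
  expect_equal(lr$p, pchisq(chi_hand, 1, lower.tail = FALSE))
  # identical groups -> chi2 0, p 1
  dup <- clinical_table(data.frame(patient_id = 1:8,
                                   time_months = rep(c(1, 3, 2, 4), 2),
                                   event = rep(c(1, 1, 1, 0), 2)))
  lr2 <- logrank_test(dup, rep(c("A", "B"), each = 4))
  expect_equal(lr2$chi2, 0, tolerance = 1e-9)
  expect_equal(lr2$p, 1, tolerance = 1e-9)
})

test_that("log-rank has power on separated exponential groups", {
  rejections <- vapply(1:20, function(r) {
    set.seed(400 + r)
    n <- 250
    t1 <- rexp(n, 0.02); t2 <- rexp(n, 0.06)
    cen <- runif(2 * n, 0, 100)
    tt <- pmin(c(t1, t2), cen)
    ev <- as.integer(c(t1, t2) <= cen)
    clin <- clinical_table(data.frame(patient_id = seq_len(2 * n),
                                      time_months = tt, event = ev))
    logrank_test(clin, rep(c("a", "b"), each = n))$p < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
})

test_that("window subsetting recodes events per the landmark definition", {
  clin <- clinical_table(data.frame(
    patient_id = paste0("p", 1:5),
    time_months = c(18, 10, 36, 24, 50),
    event = c(1L, 0L, 1L, 1L, 0L)))
  late <- window_subset(clin, recurrence_window("late", tau = 24))
  # recurrence at 18 and censoring at 10 are excluded; event at exactly
  # 24 is an early event, not at risk after the landmark
  expect_setequal(late$patient_id, c("p3", "p5"))
  expect_identical(late$event[late$patient_id == "p3"], 1L)
  expect_true(all(late$entry == 24))
  early <- window_subset(clin, recurrence_window("early", tau = 24))
  expect_identical(nrow(early), 5L)
  expect_identical(early$event, c(1L, 0L, 0L, 1L, 0L))
  expect_equal(early$time_months, c(18, 10, 24, 24, 24))
  # early + late events partition the overall events
  expect_identical(sum(early$event) + sum(late$event), sum(clin$event))
  # restart mode shifts the clock
  naive <- window_subset(clin, recurrence_window("late", tau = 24),
                         mode = "restart")
  expect_equal(naive$time_months, c(12, 26))
  expect_error(recurrence_window("late", tau = -1), "tau")
})

test_that("Cox fit recovers a known rate ratio and handles missing BCLC", {
  set.seed(77)
  n <- 2000
  z <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.02 * exp(log(2) * z))
  cen <- runif(n, 0, 80)
  clin <- clinical_table(data.frame(
    patient_id = seq_len(n), time_months = pmin(tt, cen),
    event = as.integer(tt <= cen), z = z,
    bclc = ifelse(runif(n) < 0.05, NA, sample(c("0", "A", "B", "C"), n, TRUE))))
  fit <- cox_fit(clin, "z")
  expect_gt(fit$hr, 1.8); expect_lt(fit$hr, 2.2)
  expect_true(fit$lo <= fit$hr && fit$hr <= fit$hi)
  fit2 <- cox_fit(clin, c("z", "bclc"))
  expect_identical(attr(fit2, "n_used"), sum(!is.na(clin$bclc)))
  expect_true("bclc_bc" %in% fit2$term)
  expect_error(cox_fit(clin, "nope"), "unknown covariate")
})

test_that("null covariate p-values are roughly uniform", {
  ps <- vapply(1:40, function(r) {
    set.seed(500 + r)
    n <- 120
    tt <- rexp(n, 0.03); cen <- runif(n, 0, 60)
    clin <- clinical_table(data.frame(
      patient_id = 1:n, time_months = pmin(tt, cen),
      event = as.integer(tt <= cen), x = rbinom(n, 1, 0.5)))
    cox_fit(clin, "x")$p
  }, 1)
  expect_gt(mean(ps < 0.5), 0.25)
  expect_lt(mean(ps < 0.05), 0.25)
})
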