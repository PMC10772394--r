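# Logistic LR screens and BH control.

test_that("BH adjustment matches the hand step-up on knowns and randoms", {
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5), tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.05)),
               c(0.02, 0.02, 0.04, 0.05), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), hand_bh(p), tolerance = 1e-12)
  }
  # NA entries are excluded from the family, not counted in m
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04), tolerance = 1e-12)
})

test_that("BH adjustment is monotone in the raw p values", {
  set.seed(33)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("logistic LR statistic matches the closed-form group maximum", {
  # dichotomized toy: high group 8/10 responders, low group 2/10
  y <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  x <- c(rep(1, 10), rep(0, 10))
  fit <- fit_logistic_lr(y, x)
  oracle <- logistic_group_lr(8, 10, 2, 10)
  expect_equal(fit$lr_stat, oracle, tolerance = 1e-6)
  expect_gt(fit$coefficient, 0)
  expect_equal(fit$lr_p, pchisq(oracle, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("logistic LR rejects constant biomarkers and single classes", {
  expect_error(fit_logistic_lr(c(0, 1, 0, 1), rep(2, 4)), "constant")
  expect_error(fit_logistic_lr(rep(1, 4), rnorm(4)), "both classes")
})

test_that("LR statistic is invariant to affine biomarker rescaling", {
  set.seed(41)
  y <- rbinom(200, 1, 0.4)
  x <- rnorm(200) + 0.5 * y
  cov <- data.frame(g = factor(rbinom(200, 1, 0.5)))
  a <- fit_logistic_lr(y, x, cov)
  b <- fit_logistic_lr(y, 3.7 * x - 11, cov)
  expect_equal(a$lr_stat, b$lr_stat, tolerance = 1e-7)
  expect_equal(a$coefficient, 3.7 * b$coefficient, tolerance = 1e-6)
})

test_that("complete separation is flagged, not crashed", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rnorm(10, -5), rnorm(10, 5))
  fit <- fit_logistic_lr(y, x)
  expect_true(fit$flagged)
  expect_true(is.na(fit$lr_p))
})

test_that("null biomarkers reject at the nominal rate", {
  set.seed(53)
  n <- 500
  reps <- 200
  rejections <- 0L
  for (i in seq_len(reps)) {
    y <- rbinom(n, 1, 0.35)
    x <- rnorm(n)
    fit <- fit_logistic_lr(y, x)
    if (!is.na(fit$lr_p) && fit$lr_p < 0.05) rejections <- rejections + 1L
  }
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(rejections / reps, band[1])
  expect_lte(rejections / reps, band[2])
})

test_that("the screen recovers planted effects with the right signs", {
  cfg <- sim_config(n_patients = 400L, n_analytes = 30L, n_arrays = 2L,
                    seed = 61L,
                    effect_table = data.frame(
                      analyte = c("ERBB2 Y1248", "ER alpha"),
                      beta = c(0.9, -0.9)))
  sim <- simulate_cohort(cfg)
  spots <- simulate_spots(cfg, sim$clinical, sim$truth)
  h <- harmonize(quantify_all(spots), sim$clinical, small_cfg(seed = 61L))
  recs <- association_screen(h$matrix, sim$clinical, "population",
                             small_cfg(seed = 61L))
  expect_identical(nrow(recs), 30L)
  planted <- recs[recs$analyte %in% c("ERBB2 Y1248", "ER alpha"), ]
  expect_true(all(planted$significant))
  expect_identical(planted$direction[planted$analyte == "ERBB2 Y1248"], 1)
  expect_identical(planted$direction[planted$analyte == "ER alpha"], -1)
  expect_gte(count_significant(recs), 2L)

  # column order must not matter
  recs2 <- association_screen(h$matrix[, rev(colnames(h$matrix))],
                              sim$clinical, "population",
                              small_cfg(seed = 61L))
  recs2 <- recs2[match(recs$analyte, recs2$analyte), ]
  expect_equal(recs$lr_p, recs2$lr_p, tolerance = 1e-12)
  expect_equal(recs$bh_p, recs2$bh_p, tolerance = 1e-12)
})

test_that("single-class or undersized scopes are skipped with a warning", {
  sim <- simulate_cohort(small_sim(seed = 67L))
  cl <- sim$clinical
  cl$pcr[cl$arm == "Ctr"] <- 0L
  m <- matrix(rnorm(nrow(cl) * 3), nrow(cl), 3,
              dimnames = list(cl$patient_id, c("A", "B", "C")))
  expect_warning(out <- association_screen(m, cl, "arm:Ctr", small_cfg()),
                 "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("differential screen detects planted shifts and needs 2 groups", {
  set.seed(71)
  n <- 200
  groups <- rep(c("a", "b"), each = n / 2)
  m <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("A", 1:10)))
  m[groups == "b", "A3"] <- m[groups == "b", "A3"] + 1
  out <- differential_screen(m, groups)
  expect_true(out$significant[out$analyte == "A3"])
  expect_identical(out$direction[out$analyte == "A3"], 1)
  expect_error(differential_screen(m, rep("a", n)), "two levels")
})

test_that("differential screen holds its size under permuted labels", {
  set.seed(73)
  n <- 400
  reps <- 100
  n_analytes <- 10
  nominal <- 0L
  bh_sig <- 0L
  for (i in seq_len(reps)) {
    m <- matrix(rnorm(n * n_analytes), n, n_analytes,
                dimnames = list(NULL, paste0("A", seq_len(n_analytes))))
    groups <- sample(rep(c("a", "b"), each = n / 2))
    out <- differential_screen(m, groups)
    nominal <- nominal + sum(out$nominal)
    bh_sig <- bh_sig + sum(out$significant)
  }
  total <- reps * n_analytes
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / total)
  expect_gte(nominal / total, band[1])
  expect_lte(nominal / total, band[2])
  expect_lte(bh_sig / total, 0.05)
})

test_that("group response rates match direct counting", {
  cl <- toy_clinical(8L)
  labels <- rep(c("g1", "g2"), each = 4L)
  out <- group_response_rates(labels, cl)
  expect_identical(out$n, c(4L, 4L))
  expect_equal(out$rate, c(mean(cl$pcr[1:4]), mean(cl$pcr[5:8])),
               tolerance = 1e-12)
  expect_identical(count_significant(data.frame(significant = logical(0))),
                   0L)
  all_pcr <- cl
  all_pcr$pcr <- 1L
  expect_equal(group_response_rates(rep("g", 8), all_pcr)$rate, 1)
})
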