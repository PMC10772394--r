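# Balanced-subsampling batch standardization.

test_that("stratified subsampling honours exact splits and preconditions", {
  subtypes <- rep(c("HR+HER2-", "TN"), each = 4)
  idx <- stratified_subsample(subtypes, c(0.5, 0.5, 0, 0), 4L)
  expect_length(idx, 4L)
  expect_identical(sum(subtypes[idx] == "HR+HER2-"), 2L)
  expect_identical(sum(subtypes[idx] == "TN"), 2L)

  expect_error(
    stratified_subsample(rep("TN", 5), c(1, 0, 0, 0), 3L, "array_9"),
    "array_9.*HR\\+HER2-")
})

test_that("at m = n with empirical proportions the subsample is the array", {
  set.seed(11)
  subtypes <- sample(SUBTYPE_LEVELS, 40, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1))
  emp <- as.numeric(table(factor(subtypes, SUBTYPE_LEVELS))) / 40
  idx <- stratified_subsample(subtypes, emp, 40L)
  expect_setequal(idx, seq_len(40L))
})

test_that("largest-remainder rounding preserves totals and caps strata", {
  # n * empirical proportions are integers: rounding must return them
  for (rep_i in 1:20) {
    set.seed(rep_i)
    counts <- c(rmultinom(1, 50, c(0.4, 0.3, 0.2, 0.1)))
    sizes <- rppasig:::largest_remainder(
      stats::setNames(counts / 50 * 50, SUBTYPE_LEVELS))
    expect_identical(as.integer(sizes), as.integer(counts))
    # fractional targets: total matches the rounded grand total
    m <- 17
    sizes <- rppasig:::largest_remainder(m * counts / sum(counts))
    expect_identical(sum(sizes), 17L)
  }
})

test_that("B = 1 with the full array reduces to plain column moments", {
  sim <- simulate_cohort(small_sim())
  spots <- simulate_spots(small_sim(), sim$clinical, sim$truth)
  eps <- quantify_all(spots)
  m <- eps[[1L]]
  cl <- sim$clinical
  emp <- as.numeric(table(factor(cl$subtype[match(rownames(m),
                                                  cl$patient_id)],
                                 SUBTYPE_LEVELS))) / nrow(m)
  cfg <- pipeline_config(n_subsamples = 1L, subsample_fraction = 1,
                         subtype_proportions = emp, seed = 4L)
  model <- resample_moments(m, cl, cfg)
  expect_equal(model$mu, colMeans(m), tolerance = 1e-12)
  expect_equal(model$sigma, apply(m, 2L, sd), tolerance = 1e-12)
})

test_that("a constant analyte is floored at sd_floor with a warning", {
  cl <- toy_clinical(8L)
  m <- matrix(rnorm(16), 8, 2,
              dimnames = list(cl$patient_id, c("A", "B")))
  m[, "B"] <- 3.5
  emp <- as.numeric(table(factor(cl$subtype, SUBTYPE_LEVELS))) / 8
  cfg <- pipeline_config(n_subsamples = 5L, subsample_fraction = 1,
                         subtype_proportions = emp, seed = 1L)
  expect_warning(model <- resample_moments(m, cl, cfg), "sd_floor")
  expect_identical(unname(model$sigma["B"]), cfg$sd_floor)
  z <- zscore_array(m, model)
  expect_true(all(is.finite(z)))
})

test_that("balanced moments hit the closed-form balanced mean", {
  # two subtypes with constant values 0 and 1 and even subsample size:
  # every balanced subsample mean is exactly 0.5
  cl <- validate_clinical(data.frame(
    patient_id = sprintf("P%02d", 1:30),
    hr = c(rep("pos", 18), rep("neg", 12)),
    her2 = "neg", arm = "Ctr", pcr = 0L, array_id = "a1"))
  m <- matrix(ifelse(cl$subtype == "HR+HER2-", 0, 1), 30, 1,
              dimnames = list(cl$patient_id, "A"))
  cfg <- pipeline_config(n_subsamples = 50L, subsample_fraction = 0.8,
                         subtype_proportions = c(0.5, 0.5, 0, 0), seed = 2L)
  model <- suppressWarnings(resample_moments(m, cl, cfg))
  expect_equal(unname(model$mu["A"]), 0.5, tolerance = 1e-12)
})

test_that("z-scoring maps mu to 0 and mu + sigma to 1, masks propagate", {
  cl <- toy_clinical(8L)
  m <- matrix(rnorm(24), 8, 3,
              dimnames = list(cl$patient_id, c("A", "B", "C")))
  m[2, "C"] <- NA
  emp <- as.numeric(table(factor(cl$subtype, SUBTYPE_LEVELS))) / 8
  cfg <- pipeline_config(n_subsamples = 3L, subsample_fraction = 1,
                         subtype_proportions = emp, seed = 5L)
  model <- resample_moments(m, cl, cfg)
  z <- zscore_array(m, model)
  x <- m
  x[1, ] <- model$mu
  x[3, ] <- model$mu + model$sigma
  z2 <- zscore_array(x, model)
  expect_equal(unname(z2[1, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(z2[3, ]), c(1, 1, 1), tolerance = 1e-12)
  expect_true(is.na(z[2, "C"]))

  model_small <- model
  model_small$mu <- model$mu[c("A", "B")]
  model_small$sigma <- model$sigma[c("A", "B")]
  expect_error(zscore_array(m, model_small), "lacks entries")
})

test_that("harmonization is invariant to per-array affine transforms", {
  sim <- simulate_cohort(small_sim(seed = 13L))
  spots <- simulate_spots(small_sim(seed = 13L), sim$clinical, sim$truth)
  eps <- quantify_all(spots)
  cfg <- small_cfg(seed = 13L)
  h1 <- harmonize(eps, sim$clinical, cfg)
  eps2 <- lapply(eps, function(m) {
    out <- sweep(sweep(m, 2L, runif(ncol(m), 0.5, 2), "*"),
                 2L, rnorm(ncol(m)), "+")
    attr(out, "array_id") <- attr(m, "array_id")
    out
  })
  h2 <- harmonize(eps2, sim$clinical, cfg)
  expect_equal(h1$matrix, h2$matrix, tolerance = 1e-9)
})

test_that("fixed seed gives a bit-identical harmonization model", {
  sim <- simulate_cohort(small_sim(seed = 19L))
  spots <- simulate_spots(small_sim(seed = 19L), sim$clinical, sim$truth)
  eps <- quantify_all(spots)
  cfg <- small_cfg(seed = 19L)
  expect_identical(harmonize(eps, sim$clinical, cfg)$models,
                   harmonize(eps, sim$clinical, cfg)$models)
})

test_that("combine_arrays concatenates rows and unions analytes", {
  m1 <- matrix(1:4, 2, 2, dimnames = list(c("p1", "p2"), c("A", "B")))
  m2 <- matrix(5:8, 2, 2, dimnames = list(c("p3", "p4"), c("B", "C")))
  expect_identical(combine_arrays(list(m1)),
                   matrix(as.numeric(1:4), 2, 2,
                          dimnames = list(c("p1", "p2"), c("A", "B"))))
  comb <- combine_arrays(list(m1, m2))
  expect_identical(colnames(comb), c("A", "B", "C"))
  expect_true(all(is.na(comb[c("p3", "p4"), "A"])))
  expect_true(all(is.na(comb[c("p1", "p2"), "C"])))
  expect_identical(comb["p2", "B"], 4)
  expect_identical(comb["p3", "B"], 5)
  m_dup <- m2
  rownames(m_dup) <- c("p1", "p4")
  expect_error(combine_arrays(list(m1, m_dup)), "more than one array")
})
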