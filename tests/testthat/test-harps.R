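# Youden cut points and the two-marker co-activation signature.

test_that("perfect separation yields the midpoint cut with J = 1", {
  out <- youden_cutpoint(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_identical(out$cut, 6.5)
  expect_identical(out$j, 1)
  expect_error(youden_cutpoint(1:4, rep(1, 4)), "both")
})

test_that("Youden search matches brute-force enumeration", {
  set.seed(43)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    values <- round(rnorm(n), sample(1:3, 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    got <- youden_cutpoint(values, labels)
    want <- youden_brute(values, labels)
    expect_identical(got$cut, want$cut)
    expect_equal(got$j, want$j, tolerance = 1e-12)
  }
})

test_that("Youden cut is equivariant under increasing transforms", {
  set.seed(47)
  values <- rnorm(50)
  labels <- rbinom(50, 1, plogis(values))
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  base <- youden_cutpoint(values, labels)
  mono <- youden_cutpoint(exp(values), labels)
  expect_equal(mono$j, base$j, tolerance = 1e-12)
  # the transformed cut classifies identically
  expect_identical(exp(values) >= mono$cut, values >= base$cut)
})

test_that("permuted labels give a small Youden index in expectation", {
  set.seed(51)
  values <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  js <- replicate(200, youden_cutpoint(values, sample(labels))$j)
  # the maximum-over-thresholds statistic is positively biased but small
  expect_lt(mean(js), 0.35)
  expect_gt(mean(js), 0)
})

# TN/neratinib-like derivation cohort: the two phosphoproteins are
# strongly co-activated (shared-signal correlation 0.85, as the signature's
# biology assumes), pCR probability steps from 0.05 to 0.95 at the planted
# cut z = 0.7 on both markers.
make_harps_cohort <- function(n = 150L, cut = 0.7, seed = 55L) {
  set.seed(seed)
  shared <- rnorm(n)
  m1 <- 0.35 + sqrt(0.85) * shared + sqrt(0.15) * rnorm(n)
  m2 <- 0.35 + sqrt(0.85) * shared + sqrt(0.15) * rnorm(n)
  pcr <- rbinom(n, 1, ifelse(m1 >= cut & m2 >= cut, 0.95, 0.05))
  cl <- validate_clinical(data.frame(
    patient_id = sprintf("T%03d", seq_len(n)), hr = "neg", her2 = "neg",
    arm = "N", pcr = pcr, array_id = "a1"))
  m <- cbind(`EGFR Y1173` = m1, `ERBB2 Y1248` = m2,
             other = rnorm(n))
  rownames(m) <- cl$patient_id
  list(clinical = cl, matrix = m)
}

test_that("planted step cuts are recovered in the derivation cohort", {
  coh <- make_harps_cohort()
  model <- derive_harps(coh$matrix, coh$clinical)
  expect_lt(abs(model$cuts[["EGFR Y1173"]] - 0.7), 0.1)
  expect_lt(abs(model$cuts[["ERBB2 Y1248"]] - 0.7), 0.1)
  expect_identical(model$rule, "AND")
  expect_identical(model$derivation$n, 150L)
})

test_that("derivation fails on single-class or undersized cohorts", {
  coh <- make_harps_cohort()
  cl <- coh$clinical
  cl$pcr <- 1L
  expect_error(derive_harps(coh$matrix, cl), "both pCR classes")
  expect_error(derive_harps(coh$matrix[1:8, ], coh$clinical[1:8, ]),
               "fewer than 10")
  expect_error(derive_harps(coh$matrix[, c(1, 3)], coh$clinical),
               "absent")
})

test_that("the derivation is invariant to patients outside the filter", {
  coh <- make_harps_cohort()
  model <- derive_harps(coh$matrix, coh$clinical)
  # append HER2+ control-arm patients: outside the TN/N filter
  extra_cl <- validate_clinical(data.frame(
    patient_id = sprintf("X%03d", 1:40), hr = "pos", her2 = "pos",
    arm = "Ctr", pcr = rbinom(40, 1, 0.5), array_id = "a1"))
  extra_m <- matrix(rnorm(120), 40, 3,
                    dimnames = list(extra_cl$patient_id,
                                    colnames(coh$matrix)))
  model2 <- derive_harps(rbind(coh$matrix, extra_m),
                         rbind(as.data.frame(coh$clinical),
                               as.data.frame(extra_cl)))
  expect_identical(model$cuts, model2$cuts)
})

test_that("classification uses the >= boundary and the AND rule", {
  coh <- make_harps_cohort()
  model <- derive_harps(coh$matrix, coh$clinical)
  m <- rbind(
    at_cut = c(model$cuts[1], model$cuts[2], 0),
    one_low = c(model$cuts[1] - 1e-9, model$cuts[2], 0),
    both_high = c(model$cuts[1] + 1, model$cuts[2] + 1, 0),
    masked = c(NA, model$cuts[2], 0))
  colnames(m) <- colnames(coh$matrix)
  status <- suppressMessages(harps_classify(m, model))
  expect_identical(unname(status[c("at_cut", "one_low", "both_high")]),
                   c("HARPS+", "HARPS-", "HARPS+"))
  expect_true(is.na(status[["masked"]]))
})

test_that("classification reproduces the derivation confusion counts", {
  coh <- make_harps_cohort()
  model <- derive_harps(coh$matrix, coh$clinical)
  y <- coh$clinical$pcr
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  for (mk in model$markers) {
    pos <- coh$matrix[, mk] >= model$cuts[[mk]]
    expect_identical(sum(pos & y == 1),
                     as.integer(round(model$sensitivity[[mk]] * n_pos)))
    expect_identical(sum(!pos & y == 0),
                     as.integer(round(model$specificity[[mk]] * n_neg)))
  }
})

test_that("response tables and cross-tabs are consistent counts", {
  coh <- make_harps_cohort(seed = 59L)
  model <- derive_harps(coh$matrix, coh$clinical)
  status <- harps_classify(coh$matrix, model)
  tab <- harps_response_table(status, coh$clinical)
  expect_identical(sum(tab$n), nrow(coh$clinical))
  expect_identical(sum(tab$n_pcr), sum(coh$clinical$pcr))
  expect_true(all(tab$rate >= 0 & tab$rate <= 1))
  # HARPS+ patients respond better under the planted step model
  plus <- tab$rate[tab$status == "HARPS+"]
  minus <- tab$rate[tab$status == "HARPS-"]
  expect_gt(plus, minus)

  labels <- setNames(sample(c("L1", "L2", "L3"), nrow(coh$clinical), TRUE),
                     coh$clinical$patient_id)
  xt <- harps_by_label(status, labels)
  expect_identical(sum(xt$n), nrow(coh$clinical))
  for (i in seq_len(nrow(xt))) {
    expect_identical(xt$n[i],
                     sum(status == xt$status[i] & labels == xt$label[i],
                         na.rm = TRUE))
  }
})

test_that("the HARPS model survives a JSON round trip", {
  coh <- make_harps_cohort()
  model <- derive_harps(coh$matrix, coh$clinical)
  path <- withr::local_tempfile(fileext = ".json")
  write_harps_model(model, path)
  back <- read_harps_model(path)
  expect_equal(back$cuts, model$cuts, tolerance = 1e-12)
  expect_identical(back$rule, model$rule)
  status_a <- harps_classify(coh$matrix, model)
  status_b <- harps_classify(coh$matrix, back)
  expect_identical(status_a, status_b)
})
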