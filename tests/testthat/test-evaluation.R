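test_that("metrics reproduce hand-derived values", {
  m <- compute_metrics(c(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(c(m$se, m$sp, m$acc, m$mcc), c(1, 1, 1, 1))

  m <- compute_metrics(c(tp = 25, fp = 25, tn = 25, fn = 25))
  expect_equal(m$acc, 0.5)
  expect_equal(m$mcc, 0)

  m <- compute_metrics(c(tp = 90, fn = 10, tn = 80, fp = 20))
  expect_equal(m$se, 0.9)
  expect_equal(m$sp, 0.8)
  expect_equal(m$acc, 0.85)
  expect_equal(m$mcc, (90 * 80 - 20 * 10) / sqrt(110 * 100 * 100 * 90),
               tolerance = 1e-12)
  expect_equal(round(m$mcc, 4), 0.7035)
})

test_that("zero denominators are flagged, not propagated as NaN", {
  m <- compute_metrics(c(tp = 0, fp = 5, tn = 5, fn = 0))
  expect_true(is.na(m$se))
  expect_true(m$se_undefined)
  expect_false(m$sp_undefined)
  expect_equal(m$mcc, 0)
  expect_true(m$mcc_zero_denom)

  expect_error(compute_metrics(c(tp = -1, fp = 0, tn = 1, fn = 0)), "non-negative")
  expect_error(compute_metrics(c(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
})

test_that("metric identities and symmetries hold on random confusion tables", {
  withr::local_seed(23)
  for (rep in 1:1000) {
    cts <- as.list(stats::setNames(sample(0:60, 4, replace = TRUE),
                                   c("tp", "fp", "tn", "fn")))
    if (with(cts, tp + fp + tn + fn) == 0) next
    m <- compute_metrics(cts)
    p <- cts$tp + cts$fn
    n <- cts$tn + cts$fp
    if (p > 0 && n > 0) {
      expect_equal(m$acc, (m$se * p + m$sp * n) / (p + n), tolerance = 1e-12)
    }
    # class swap: TP<->TN, FP<->FN leaves ACC/MCC fixed, swaps SE/SP
    sw <- compute_metrics(list(tp = cts$tn, fp = cts$fn, tn = cts$tp, fn = cts$fp))
    expect_equal(sw$acc, m$acc, tolerance = 1e-12)
    expect_equal(sw$mcc, m$mcc, tolerance = 1e-12)
    expect_equal(sw$se, m$sp, tolerance = 1e-12)
    expect_equal(sw$sp, m$se, tolerance = 1e-12)
  }
})

test_that("confusion counting agrees with a brute-force recount", {
  withr::local_seed(31)
  truth <- sample(0:1, 200, replace = TRUE)
  pred <- sample(0:1, 200, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  brute <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in seq_along(truth)) {
    key <- if (truth[i] == 1 && pred[i] == 1) "tp"
           else if (truth[i] == 0 && pred[i] == 1) "fp"
           else if (truth[i] == 0 && pred[i] == 0) "tn"
           else "fn"
    brute[key] <- brute[key] + 1
  }
  expect_equal(unlist(cc), brute)
  expect_equal(sum(unlist(cc)), 200)
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "0/1")
})

small_cfg <- function() {
  encoder_config(lambda_apaac = 2, lambda_paac = 2,
                 kmax_ksctriad = 0, kmax_cksaagp = 1)
}

test_that("cross-validation pools exactly the per-fold counts and covers every sequence", {
  ds <- generate_synthetic(n_pos = 15, n_neg = 15, length_range = c(30, 60),
                           delta = 0.8, seed = 11)
  cv <- cross_validate(ds, small_cfg(), n_folds = 3, seed = 11)
  expect_equal(nrow(cv$predictions), 30)
  expect_setequal(cv$predictions$id, ds$id)
  pooled_counts <- cv$pooled[c("tp", "fp", "tn", "fn")]
  fold_sums <- colSums(cv$per_fold[c("tp", "fp", "tn", "fn")])
  expect_equal(unlist(pooled_counts), fold_sums)
  expect_equal(glance(cv)$n_folds, 3)
  expect_equal(nrow(tidy(cv)), 3)
})

test_that("a minimal 2-fold CV on 4 sequences runs and evaluates all of them", {
  withr::local_seed(2)
  ds <- tibble::tibble(
    id = paste0("s", 1:4),
    residues = vapply(rep(30, 4), rand_seq, character(1)),
    label = c(1L, 1L, 0L, 0L)
  )
  cv <- cross_validate(ds, small_cfg(), n_folds = 2, seed = 1)
  expect_equal(sum(unlist(cv$pooled[c("tp", "fp", "tn", "fn")])), 4)
})

test_that("holdout evaluation trains once, guards leakage, and rejects empty tests", {
  tr <- generate_synthetic(n_pos = 12, n_neg = 12, length_range = c(30, 60),
                           delta = 0.9, seed = 21, id_prefix = "tr_")
  te <- generate_synthetic(n_pos = 8, n_neg = 8, length_range = c(30, 60),
                           delta = 0.9, seed = 22, id_prefix = "te_")
  h <- evaluate_holdout(tr, te, small_cfg(), seed = 5)
  expect_s3_class(h, "mhc_holdout")
  expect_equal(sum(unlist(h$metrics[c("tp", "fp", "tn", "fn")])), 16)
  expect_gt(h$metrics$acc, 0.5)

  expect_error(evaluate_holdout(tr, tr, small_cfg()), "share")
  resub <- evaluate_holdout(tr, tr, small_cfg(), allow_overlap = TRUE)
  expect_gte(resub$metrics$acc, h$metrics$acc - 0.2)
  expect_error(evaluate_holdout(tr, te[0, ], small_cfg()), "empty")
})

test_that("metrics JSON serialization carries counts, metrics and config", {
  ds <- generate_synthetic(n_pos = 10, n_neg = 10, length_range = c(30, 50),
                           delta = 0.8, seed = 31)
  cv <- cross_validate(ds, small_cfg(), n_folds = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(cv, path)
  got <- jsonlite::read_json(path)
  expect_equal(got$protocol, "cross_validation")
  expect_equal(got$pooled$acc, cv$pooled$acc)
  expect_length(got$per_fold, 2)
  expect_equal(got$config$lambda_apaac, 2)
})
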