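test_that("auc_roc matches its boundary examples and the undefined sentinel", {
  expect_equal(auc_roc(c(1, 1, 0, 0), c(.9, .8, .2, .1)), 1.0)
  expect_equal(auc_roc(c(1, 0, 1, 0), c(.5, .5, .5, .5)), 0.5)
  expect_equal(auc_roc(c(0, 0, 1, 1), c(.9, .8, .2, .1)), 0.0)
  expect_true(is.na(auc_roc(c(1, 1), c(.2, .3))))
  expect_true(is.na(auc_roc(c(0, 0), c(.2, .3))))
})

test_that("auc_roc equals brute-force pair counting on random instances", {
  set.seed(81)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    expect_equal(auc_roc(labels, scores),
                 oracle_auc_paircount(labels, scores))
  }
})

test_that("auc_roc is invariant under strictly monotone score transforms", {
  set.seed(82)
  labels <- rbinom(80, 1, 0.4)
  scores <- rnorm(80)
  a <- auc_roc(labels, scores)
  expect_equal(auc_roc(labels, exp(scores)), a)
  expect_equal(auc_roc(labels, 3 * scores - 7), a)
  expect_equal(auc_roc(labels, atan(scores)), a)
})

test_that("auc_roc cross-checks against an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  labels <- rbinom(100, 1, 0.5)
  scores <- rnorm(100)
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(auc_roc(labels, scores), want, tolerance = 1e-12)
})

test_that("spearman_r matches the mid-rank oracle, ties included", {
  expect_equal(spearman_r(1:10, 2 * (1:10) + 1), 1.0)
  expect_equal(spearman_r(1:10, -(1:10)), -1.0)
  expect_equal(spearman_r(c(1, 2, 2, 4), c(3, 1, 2, 4)),
               oracle_spearman_midrank(c(1, 2, 2, 4), c(3, 1, 2, 4)))
  set.seed(84)
  for (i in 1:50) {
    n <- sample(3:50, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)
    expect_equal(spearman_r(x, y), oracle_spearman_midrank(x, y))
  }
  expect_true(is.na(spearman_r(rep(1, 5), 1:5)))
  expect_true(is.na(spearman_r(1, 2)))
})

make_pred <- function(allele, ic50, y_pred, inequality = "EQ") {
  tibble::tibble(
    allele = allele,
    peptide = rand_peps(length(ic50), 9, 9),
    ic50_nm = ic50,
    inequality = inequality,
    kind = ifelse(inequality == "EQ", "quantitative", "qualitative"),
    y_pred = y_pred
  )
}

test_that("for a single allele, mean and overall aggregates are identical", {
  set.seed(85)
  pred <- make_pred("A", exp(runif(40, 0, 10)), rnorm(40))
  rep <- evaluate_predictions(pred)
  expect_identical(rep$aggregate$mean, rep$aggregate$overall)
})

test_that("mean weights alleles equally while overall follows the pooled rows", {
  set.seed(86)
  # allele A: 10 rows, perfectly ranked (AUC 1); allele B: 1000 rows, all
  # scores tied (AUC 0.5)
  a <- make_pred("A", c(rep(100, 5), rep(5000, 5)),
                 c(rep(2, 5), rep(1, 5)))
  b <- make_pred("B", rep(c(100, 5000), 500), rep(0, 1000))
  pred <- dplyr::bind_rows(a, b)
  rep <- evaluate_predictions(pred, binder_threshold_nm = 500)
  auc_mean <- rep$aggregate$mean[rep$aggregate$metric == "auc"]
  auc_overall <- rep$aggregate$overall[rep$aggregate$metric == "auc"]
  expect_equal(auc_mean, 0.75)
  labs <- binder_label(pred$ic50_nm, 500)
  expect_equal(auc_overall, oracle_auc_paircount(labs, pred$y_pred))
  expect_lt(auc_overall, 0.75)  # dominated by the big tied allele
})

test_that("alleles with undefined metrics are excluded from the mean, pooled for overall", {
  set.seed(87)
  ok <- make_pred("A", exp(runif(30, 0, 10)), rnorm(30))
  allpos <- make_pred("B", rep(10, 8), rnorm(8))  # all binders: AUC undefined
  rep <- evaluate_predictions(dplyr::bind_rows(ok, allpos))
  expect_equal(rep$excluded$auc, "B")
  per_ok <- rep$per_allele$auc[rep$per_allele$allele == "A"]
  expect_equal(rep$aggregate$mean[rep$aggregate$metric == "auc"], per_ok)
  # B's rows still enter the pooled overall metric
  labs <- binder_label(dplyr::bind_rows(ok, allpos)$ic50_nm, 500)
  expect_equal(rep$aggregate$overall[rep$aggregate$metric == "auc"],
               oracle_auc_paircount(labs, dplyr::bind_rows(ok, allpos)$y_pred))
})

test_that("only quantitative records enter Spearman; qualitative ones enter AUC", {
  set.seed(88)
  quant <- make_pred("A", exp(runif(30, 0, 10)), rnorm(30))
  qual <- make_pred("A", rep(50000, 10), rnorm(10), inequality = "GT")
  rep <- evaluate_predictions(dplyr::bind_rows(quant, qual))
  expect_equal(rep$per_allele$n_quant, 30)
  want_sp <- oracle_spearman_midrank(quant$ic50_nm, -quant$y_pred)
  expect_equal(rep$per_allele$spearman, want_sp)
  # all-qualitative: Spearman undefined, AUC still defined
  rep2 <- evaluate_predictions(dplyr::bind_rows(
    make_pred("A", rep(50000, 10), rnorm(10), inequality = "GT"),
    make_pred("A", rep(10, 10), rnorm(10), inequality = "LT")
  ))
  expect_true(is.na(rep2$per_allele$spearman))
  expect_false(is.na(rep2$per_allele$auc))
})

test_that("mean aggregation is invariant to duplicating one allele; overall is not", {
  set.seed(89)
  a <- make_pred("A", exp(runif(20, 0, 10)), rnorm(20))
  b <- make_pred("B", exp(runif(20, 0, 10)), rnorm(20))
  base <- dplyr::bind_rows(a, b)
  dup <- dplyr::bind_rows(a, b, b)  # duplicate all of B's rows
  g1 <- glance(evaluate_predictions(base))
  g2 <- glance(evaluate_predictions(dup))
  expect_equal(g1$mean_auc, g2$mean_auc, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g1$overall_auc, g2$overall_auc)))
})

test_that("bootstrap_ci is deterministic, contains the point, zero-width when stable", {
  set.seed(90)
  sep <- make_pred("A", c(rep(100, 15), rep(5000, 15)),
                   c(rnorm(15, 5), rnorm(15, 0)))  # perfectly separated
  stat <- function(d) auc_roc(binder_label(d$ic50_nm, 500), d$y_pred)
  ci <- bootstrap_ci(sep, stat, B = 200, seed = 7)
  expect_equal(ci$point, 1)
  expect_equal(ci$lo, 1)
  expect_equal(ci$hi, 1)
  noisy <- make_pred("A", exp(runif(60, 0, 10)), rnorm(60))
  sp <- function(d) spearman_r(d$ic50_nm, -d$y_pred)
  c1 <- bootstrap_ci(noisy, sp, B = 200, seed = 8)
  c2 <- bootstrap_ci(noisy, sp, B = 200, seed = 8)
  expect_identical(c1, c2)
  expect_lte(c1$lo, c1$point)
  expect_gte(c1$hi, c1$point)
  expect_error(bootstrap_ci(noisy, sp, B = 50), "at least 100")
})

test_that("bootstrap interval width shrinks roughly like 1/sqrt(n)", {
  stat <- function(d) auc_roc(d$label, d$score)
  widths <- vapply(c(100, 400, 1600), function(n) {
    set.seed(91)
    lab <- rep(0:1, n / 2)
    d <- tibble::tibble(allele = "A", label = lab,
                        score = rnorm(n, mean = lab))
    ci <- bootstrap_ci(d, stat, B = 300, seed = 9)
    ci$hi - ci$lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], widths[1] / 2)
})

test_that("multi_run_report applies the conservative error rule", {
  runs <- tibble::tibble(point = c(0.80, 0.82), lo = c(0.78, 0.80),
                         hi = c(0.83, 0.83))
  out <- multi_run_report(runs)
  expect_equal(out$mean, 0.81)
  expect_equal(out$error, 0.03)
  expect_equal(out$k, 2L)
  # identical runs: mean is the common value, error the CI half-width
  same <- tibble::tibble(point = rep(0.9, 3), lo = rep(0.88, 3),
                         hi = rep(0.92, 3))
  out2 <- multi_run_report(same)
  expect_equal(out2$mean, 0.9)
  expect_equal(out2$error, 0.02)
  expect_error(multi_run_report(runs[1, ]), "at least 2")
  expect_error(multi_run_report(tibble::tibble(point = 1)), "columns")
})

test_that("similarity audit flags same-length pairs at or above the threshold", {
  # identical 9-mers are always flagged
  out <- similarity_overlap_audit("SIINFEKLA", c("SIINFEKLA", "LLDVTAAVL"))
  expect_equal(out$peptide, "SIINFEKLA")
  expect_equal(out$identity, 1)
  # 7/9 matching positions = 0.778 < 0.8: not flagged
  expect_equal(nrow(similarity_overlap_audit("AAAAAAAAA", "AAAAAAACC", 0.8)),
               0L)
  # 8/9 = 0.889 >= 0.8: flagged
  expect_equal(nrow(similarity_overlap_audit("AAAAAAAAA", "AAAAAAAAC", 0.8)),
               1L)
  # different lengths are never compared, whatever the identity
  expect_equal(nrow(similarity_overlap_audit("AAAAAAAAA", "AAAAAAAA", 0.5)),
               0L)
  expect_error(similarity_overlap_audit(character(0), "AAA"), "non-empty")
})

test_that("tidiers expose per-allele and aggregate views", {
  set.seed(92)
  pred <- dplyr::bind_rows(
    make_pred("A", exp(runif(30, 0, 10)), rnorm(30)),
    make_pred("B", exp(runif(30, 0, 10)), rnorm(30))
  )
  rep <- evaluate_predictions(pred)
  td <- tidy(rep)
  expect_equal(nrow(td), 2L)
  expect_true(all(c("allele", "auc", "spearman") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_alleles, 2L)
  expect_s3_class(autoplot(rep), "ggplot")
})
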