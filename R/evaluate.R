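#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) identity: the probability that a
#' randomly chosen positive scores above a randomly chosen negative, with
#' ties counted half. Returns the explicit undefined sentinel `NA` when only
#' one class is present (such alleles are excluded from mean aggregates and
#' listed in the report's exclusion flags rather than raising an error).
#'
#' @param labels 0/1 (or logical) labels.
#' @param scores Numeric scores; higher means more positive.
#' @return AUC in \[0, 1\], or `NA` if undefined.
#' @examples
#' auc_roc(c(1, 1, 0, 0), c(.9, .8, .2, .1))  # 1
#' auc_roc(c(1, 0), c(.5, .5))                # 0.5 (all tied)
#' @export
auc_roc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]
  scores <- scores[keep]
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties), the standard
#' measure of agreement between measured and predicted affinity rankings.
#' Returns the undefined sentinel `NA` for fewer than two pairs or when
#' either vector has zero rank variance (e.g. all-constant predictions).
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
spearman_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) return(NA_real_)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

# Required columns of a prediction set.
check_prediction_set <- function(pred) {
  needed <- c("allele", "peptide", "ic50_nm", "inequality", "kind", "y_pred")
  missing <- setdiff(needed, names(pred))
  if (length(missing) > 0L) {
    stop("prediction set is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(pred) == 0L) stop("prediction set is empty", call. = FALSE)
  invisible(pred)
}

#' Assemble a prediction set
#'
#' Runs a trained model (or ensemble) on the peptides of a set of affinity
#' records and binds predictions to the measured values: the tabular unit
#' the evaluation harness consumes and the unit this package always exports
#' (one row per peptide, no silent drops).
#'
#' @param object A `pep_affinity_model` or `pep_affinity_ensemble`.
#' @param records Affinity records of the test set (same allele).
#' @return A tibble with columns `allele`, `peptide`, `ic50_nm`,
#'   `inequality`, `kind`, `y_true`, `y_pred`, `ic50_pred_nm`.
#' @export
prediction_set <- function(object, records) {
  validate_affinity(records)
  pr <- stats::predict(object, records$peptide)
  tibble::tibble(
    allele = records$allele,
    peptide = records$peptide,
    ic50_nm = records$ic50_nm,
    inequality = records$inequality,
    kind = records$kind,
    y_true = ic50_to_target(records$ic50_nm, object$cap_nm),
    y_pred = pr$y_pred,
    ic50_pred_nm = pr$ic50_pred_nm
  )
}

#' Binder labels for quantitative and censored records
#'
#' Derives 0/1 binder labels at a threshold from affinity records,
#' respecting inequality qualifiers: quantitative (`EQ`) records use the
#' strict [binder_label()] rule; `LT b` records (true IC50 below the bound)
#' are binders whenever `b <= threshold`; `GT b` records are non-binders
#' whenever `b >= threshold`. A censored record whose bound falls on the
#' uninformative side of the threshold is labelled from the bound itself
#' (the only value available) — avoid such configurations.
#'
#' @param records Data frame with `ic50_nm` and `inequality` columns.
#' @param threshold_nm Binder threshold in nM.
#' @return Integer 0/1 labels.
#' @export
binder_label_records <- function(records, threshold_nm = 500) {
  ifelse(
    records$inequality == "LT",
    as.integer(records$ic50_nm <= threshold_nm),
    ifelse(
      records$inequality == "GT",
      as.integer(records$ic50_nm < threshold_nm),
      binder_label(records$ic50_nm, threshold_nm)
    )
  )
}

# Per-allele AUC and Spearman. AUC uses binder labels derived from the IC50
# (for qualitative records, from the censoring bound and its direction);
# Spearman uses only quantitative (EQ) measurements.
allele_metric_row <- function(d, binder_threshold_nm) {
  quant <- d$inequality == "EQ"
  tibble::tibble(
    n = nrow(d),
    n_quant = sum(quant),
    auc = auc_roc(binder_label_records(d, binder_threshold_nm), d$y_pred),
    spearman = spearman_r(d$ic50_nm[quant], -d$y_pred[quant])
  )
}

#' Allele-wise and aggregate evaluation of a prediction set
#'
#' Computes AUC ROC (binders defined by `binder_threshold_nm`, strictly
#' below) and Spearman r (quantitative records only) per allele, and
#' aggregates them two ways: `mean` — the unweighted average of the defined
#' per-allele metrics (macro average; every allele counts equally) — and
#' `overall` — the metric on all rows pooled across alleles (micro average;
#' large test sets dominate, and scores are implicitly assumed comparable
#' across alleles). Alleles where a metric is undefined (single-class
#' labels, constant ranks, fewer than 2 quantitative pairs) are excluded
#' from the mean aggregate and listed in `excluded`; their rows still enter
#' the pooled overall metric when it is defined there.
#'
#' @param pred A prediction set (see [prediction_set()]).
#' @param binder_threshold_nm Binder threshold in nM (strictly below).
#'   Default 500 (MHC class I convention).
#' @param spearman_min_quant Allele-wise Spearman is reported only for
#'   alleles with more than this many quantitative measurements (`NA`
#'   otherwise in the per-allele table; aggregates are unaffected).
#'   Default 25.
#' @return An object of class `pep_metric_report`: list with `per_allele`
#'   (tibble), `aggregate` (tibble of metric x mode), `excluded` (named
#'   list of allele vectors), `binder_threshold_nm`.
#' @export
evaluate_predictions <- function(pred, binder_threshold_nm = 500,
                                 spearman_min_quant = 25) {
  check_prediction_set(pred)
  per <- dplyr::group_modify(
    dplyr::group_by(pred, .data$allele),
    ~ allele_metric_row(.x, binder_threshold_nm)
  )
  per <- dplyr::ungroup(per)
  excluded <- list(
    auc = per$allele[is.na(per$auc)],
    spearman = per$allele[is.na(per$spearman)]
  )
  quant <- pred$inequality == "EQ"
  agg <- tibble::tibble(
    metric = c("auc", "spearman"),
    mean = c(mean(per$auc, na.rm = TRUE), mean(per$spearman, na.rm = TRUE)),
    overall = c(
      auc_roc(binder_label_records(pred, binder_threshold_nm), pred$y_pred),
      spearman_r(pred$ic50_nm[quant], -pred$y_pred[quant])
    )
  )
  agg$mean[is.nan(agg$mean)] <- NA_real_
  per$spearman_shown <- !is.na(per$spearman) & per$n_quant > spearman_min_quant
  structure(
    list(per_allele = per, aggregate = agg, excluded = excluded,
         binder_threshold_nm = binder_threshold_nm),
    class = "pep_metric_report"
  )
}

#' @export
print.pep_metric_report <- function(x, ...) {
  cat("<pep_metric_report>", nrow(x$per_allele), "allele(s); binder threshold",
      x$binder_threshold_nm, "nM\n")
  agg <- as.data.frame(x$aggregate)
  print(agg, row.names = FALSE, digits = 4)
  if (length(x$excluded$auc) > 0) {
    cat("  AUC undefined for:", paste(x$excluded$auc, collapse = ", "), "\n")
  }
  if (length(x$excluded$spearman) > 0) {
    cat("  Spearman undefined for:",
        paste(x$excluded$spearman, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate a single metric over a prediction set
#'
#' Convenience scalar version of the aggregation in
#' [evaluate_predictions()]: `mean` averages defined per-allele values,
#' `overall` evaluates the metric on the pooled rows.
#'
#' @inheritParams evaluate_predictions
#' @param metric `"auc"` or `"spearman"`.
#' @param mode `"mean"` or `"overall"`.
#' @return Scalar metric value (`NA` if undefined).
#' @export
aggregate_metric <- function(pred, metric = c("auc", "spearman"),
                             mode = c("mean", "overall"),
                             binder_threshold_nm = 500) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  rep <- evaluate_predictions(pred, binder_threshold_nm)
  rep$aggregate[[mode]][rep$aggregate$metric == metric]
}

#' Empirical bootstrap confidence interval for a prediction-set metric
#'
#' Resamples prediction rows with replacement, stratified within allele (so
#' the allele composition of the set is preserved), recomputes the metric on
#' each of `B` replicates, and returns the 95% (or `level`) empirical
#' bootstrap interval. The default `"basic"` type is the pivot interval
#' `(2*theta_hat - q_hi, 2*theta_hat - q_lo)` built from the replicate
#' quantiles; `"percentile"` returns the replicate quantiles directly for
#' comparison. Replicates on which the metric is undefined are dropped; if
#' they exceed 1% of `B` a warning reports the count. Deterministic given
#' `seed`.
#'
#' @inheritParams evaluate_predictions
#' @param statistic A function of a prediction-set tibble returning one
#'   number, e.g. `function(d) aggregate_metric(d, "auc", "overall")`.
#' @param B Number of bootstrap replicates, at least 100. Default 1000.
#' @param seed Integer seed for the resampling.
#' @param level Confidence level. Default 0.95.
#' @param type `"basic"` (empirical/pivot, default) or `"percentile"`.
#' @return A tibble with `point`, `lo`, `hi`, `B`, `n_failed`, `level`,
#'   `type`.
#' @export
bootstrap_ci <- function(pred, statistic, B = 1000L, seed = 1L,
                         level = 0.95, type = c("basic", "percentile")) {
  if (!"allele" %in% names(pred) || nrow(pred) == 0L) {
    stop("pred must be a non-empty data frame with an `allele` column",
         call. = FALSE)
  }
  type <- match.arg(type)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  point <- statistic(pred)
  if (is.na(point)) {
    stop("statistic is undefined on the full prediction set", call. = FALSE)
  }
  idx_by_allele <- split(seq_len(nrow(pred)), pred$allele)
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      take <- unlist(lapply(idx_by_allele, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      statistic(pred[take, , drop = FALSE])
    }, numeric(1))
  })
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.01 * B) {
    warning("metric undefined on ", n_failed, " of ", B,
            " bootstrap replicates; they were dropped", call. = FALSE)
  }
  reps <- reps[!is.na(reps)]
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  ci <- if (type == "basic") c(2 * point - q[2], 2 * point - q[1]) else q
  tibble::tibble(point = point, lo = ci[1], hi = ci[2], B = as.integer(B),
                 n_failed = as.integer(n_failed), level = level, type = type)
}

#' Summarise repeated single-model runs
#'
#' For single (non-ensemble) models, performance is conventionally reported
#' as the mean point estimate across k independent runs together with a
#' conservative error: the maximum over runs of the larger deviation of the
#' point estimate from its bootstrap interval bounds.
#'
#' @param runs A data frame with one row per run and metric, columns
#'   `metric` (optional; a single unnamed metric is assumed otherwise),
#'   `point`, `lo`, `hi`.
#' @return A tibble per metric: `mean`, `error`, `k`.
#' @examples
#' runs <- tibble::tibble(point = c(0.80, 0.82),
#'                        lo = c(0.78, 0.80), hi = c(0.83, 0.83))
#' multi_run_report(runs)  # mean 0.81, error 0.03
#' @export
multi_run_report <- function(runs) {
  needed <- c("point", "lo", "hi")
  missing <- setdiff(needed, names(runs))
  if (length(missing) > 0L) {
    stop("runs must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!"metric" %in% names(runs)) runs$metric <- "metric"
  if (any(runs$lo > runs$point | runs$hi < runs$point)) {
    stop("each interval must contain its point estimate", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(runs, .data$metric),
    mean = mean(.data$point),
    error = max(pmax(.data$point - .data$lo, .data$hi - .data$point)),
    k = dplyr::n(),
    .groups = "drop"
  )
  if (any(out$k < 2)) {
    stop("multi_run_report needs at least 2 runs per metric", call. = FALSE)
  }
  out
}

# Byte matrix (length x n) for a set of equal-length peptides.
peptide_byte_matrix <- function(peptides) {
  vapply(peptides, utf8ToInt, integer(nchar(peptides[1])), USE.NAMES = FALSE)
}

#' Audit train/test overlap by same-length sequence identity
#'
#' Flags test peptides that share at least `threshold` positional sequence
#' identity (matching positions divided by length) with a training peptide
#' of the same length — the redundancy criterion used to decontaminate
#' benchmark splits (different-length pairs are never compared). Sound
#' generalisation estimates require this overlap to be empty.
#'
#' @param train,test Affinity-record data frames (with a `peptide` column)
#'   or bare character vectors of peptides; both non-empty.
#' @param threshold Identity fraction at or above which a pair is flagged.
#'   Default 0.8.
#' @return A tibble of flagged test peptides: `peptide`, `train_peptide`
#'   (the best same-length match), `identity`. Zero rows means the split is
#'   clean.
#' @export
similarity_overlap_audit <- function(train, test, threshold = 0.8) {
  pep_of <- function(x) if (is.character(x)) x else x$peptide
  train_pep <- unique(pep_of(train))
  test_pep <- unique(pep_of(test))
  if (length(train_pep) == 0L || length(test_pep) == 0L) {
    stop("both train and test must be non-empty", call. = FALSE)
  }
  out <- list()
  train_by_len <- split(train_pep, nchar(train_pep))
  test_by_len <- split(test_pep, nchar(test_pep))
  for (len in intersect(names(train_by_len), names(test_by_len))) {
    L <- as.integer(len)
    tr_mat <- peptide_byte_matrix(train_by_len[[len]])
    for (p in test_by_len[[len]]) {
      ident <- colSums(tr_mat == utf8ToInt(p)) / L
      best <- which.max(ident)
      if (ident[best] >= threshold) {
        out[[length(out) + 1L]] <- tibble::tibble(
          peptide = p,
          train_peptide = train_by_len[[len]][best],
          identity = ident[best]
        )
      }
    }
  }
  if (length(out) == 0L) {
    tibble::tibble(peptide = character(), train_peptide = character(),
                   identity = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}
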