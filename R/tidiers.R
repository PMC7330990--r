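#' Tidy an evaluation report
#'
#' One row per allele with its sample sizes and metrics, broom-style.
#'
#' @param x A `pep_metric_report` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A tibble: `allele`, `n`, `n_quant`, `auc`, `spearman`,
#'   `spearman_shown`.
#' @export
tidy.pep_metric_report <- function(x, ...) {
  x$per_allele
}

#' Glance at an evaluation report
#'
#' @inheritParams tidy.pep_metric_report
#' @return A one-row tibble with `mean_auc`, `mean_spearman`, `overall_auc`,
#'   `overall_spearman`, `n_alleles`, `n_excluded_auc`,
#'   `n_excluded_spearman`.
#' @export
glance.pep_metric_report <- function(x, ...) {
  a <- x$aggregate
  tibble::tibble(
    mean_auc = a$mean[a$metric == "auc"],
    mean_spearman = a$mean[a$metric == "spearman"],
    overall_auc = a$overall[a$metric == "auc"],
    overall_spearman = a$overall[a$metric == "spearman"],
    n_alleles = nrow(x$per_allele),
    n_excluded_auc = length(x$excluded$auc),
    n_excluded_spearman = length(x$excluded$spearman)
  )
}

#' Tidy a fitted affinity model
#'
#' @param x A `pep_affinity_model` from [finetune_regressor()].
#' @param ... Unused.
#' @return The per-epoch loss history tibble.
#' @export
tidy.pep_affinity_model <- function(x, ...) {
  x$history
}

#' Glance at a fitted affinity model
#'
#' @inheritParams tidy.pep_affinity_model
#' @return One-row tibble: `allele`, `n_train`, `n_valid`, `pretrained`,
#'   `final_train_loss`, `final_valid_loss`, `n_parameters`.
#' @export
glance.pep_affinity_model <- function(x, ...) {
  tibble::tibble(
    allele = x$allele,
    n_train = x$n_train,
    n_valid = x$n_valid,
    pretrained = x$pretrained,
    final_train_loss = utils::tail(x$history$train_loss, 1),
    final_valid_loss = utils::tail(x$history$valid_loss, 1),
    n_parameters = n_parameters(x$model)
  )
}

#' Tidy a pretrained language-model fit
#'
#' @param x A `pep_lm_fit` from [pretrain_lm()].
#' @param ... Unused.
#' @return The per-epoch training cross-entropy history tibble.
#' @export
tidy.pep_lm_fit <- function(x, ...) {
  x$history
}

#' Glance at a pretrained language-model fit
#'
#' @inheritParams tidy.pep_lm_fit
#' @return One-row tibble: held-out `perplexity`, `accuracy`, `n_holdout`,
#'   `n_parameters`.
#' @export
glance.pep_lm_fit <- function(x, ...) {
  tibble::tibble(
    perplexity = x$metrics$perplexity,
    accuracy = x$metrics$accuracy,
    n_holdout = x$metrics$n_holdout,
    n_parameters = n_parameters(x$model)
  )
}

#' Plot an evaluation report
#'
#' Allele-wise metrics as points with the aggregate mean and overall values
#' as horizontal reference lines.
#'
#' @param object A `pep_metric_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pep_metric_report <- function(object, ...) {
  per <- tidyr::pivot_longer(object$per_allele, c("auc", "spearman"),
                             names_to = "metric", values_to = "value")
  agg <- tidyr::pivot_longer(object$aggregate, c("mean", "overall"),
                             names_to = "mode", values_to = "value")
  ggplot2::ggplot(per, ggplot2::aes(x = .data$allele, y = .data$value)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(
      data = agg,
      ggplot2::aes(yintercept = .data$value, linetype = .data$mode),
      na.rm = TRUE
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, linetype = "aggregate") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a learning-rate range test
#'
#' Smoothed loss against learning rate (log scale) with the suggested base
#' rate marked.
#'
#' @param object A `pep_lr_range` from [lr_range_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pep_lr_range <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$lr, y = .data$smooth)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$suggestion, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "learning rate", y = "smoothed training loss") +
    ggplot2::theme_bw()
}

#' Plot a training history
#'
#' Per-epoch training (and, when available, validation) loss curves.
#'
#' @param object A `pep_affinity_model` or `pep_lm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pep_affinity_model <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(y = "censored MSE") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.pep_affinity_model
#' @export
autoplot.pep_lm_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$train_ce)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "training cross-entropy") +
    ggplot2::theme_bw()
}
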