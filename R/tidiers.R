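#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted purity ensemble
#'
#' One row per ensemble member with its plan position and validation
#' performance on the original purity scale.
#'
#' @param x a `purity_ensemble`.
#' @param ... unused.
#' @return A tibble: `model`, `repetition`, `fold`, `n_train`, `n_valid`,
#'   `n_trees`, `best_iter`, `val_rmse`, `val_pearson`.
#' @method tidy purity_ensemble
#' @export
tidy.purity_ensemble <- function(x, ...) x$val_metrics

#' One-row ensemble summary
#'
#' @param x a `purity_ensemble`.
#' @param ... unused.
#' @return A one-row tibble: ensemble dimensions, configuration, and
#'   mean/median validation metrics.
#' @method glance purity_ensemble
#' @export
glance.purity_ensemble <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$models),
    n_repetitions = x$plan$n_repetitions,
    n_folds = x$plan$n_folds,
    n_genes = length(x$gene_symbols),
    n_skipped = nrow(x$skipped),
    learning_rate = x$config$learning_rate,
    max_depth = x$config$max_depth,
    mean_val_rmse = mean(x$val_metrics$val_rmse),
    median_val_rmse = stats::median(x$val_metrics$val_rmse),
    mean_val_pearson = mean(x$val_metrics$val_pearson),
    median_val_pearson = stats::median(x$val_metrics$val_pearson)
  )
}

#' Tidy / summarize an evaluation result
#'
#' @param x a `purity_eval` from [evaluate_predictions()].
#' @param ... unused.
#' @return `tidy()`: the per-model metric tibble; `glance()`: one row with
#'   the bagged predictor's final RMSE / Pearson / Spearman and sample size.
#' @method tidy purity_eval
#' @export
tidy.purity_eval <- function(x, ...) x$per_model

#' @rdname tidy.purity_eval
#' @method glance purity_eval
#' @export
glance.purity_eval <- function(x, ...) {
  tibble::tibble(rmse = x$final[["rmse"]], pearson = x$final[["pearson"]],
                 spearman = x$final[["spearman"]], n = x$n,
                 n_models = nrow(x$per_model))
}

#' Tidy / summarize a permutation test
#'
#' @param x a `permutation_result`.
#' @param ... unused.
#' @return `tidy()`: one row per permutation statistic; `glance()`: one row
#'   with the observed statistic, B and the empirical p-value.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$B), statistic = x$null)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 B = x$B, p_value = x$p_value)
}

#' Predicted-versus-observed purity scatterplot
#'
#' @param object a `purity_prediction`.
#' @param truth a [purity_vector()] (original scale) with the observed
#'   purities of the predicted samples.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot purity_prediction
#' @export
autoplot.purity_prediction <- function(object, truth, ...) {
  y <- stats::setNames(truth$purity, truth$sample_id)[object$sample_id]
  df <- tibble::tibble(observed = unname(y), predicted = object$purity_pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Observed tumor purity", y = "Predicted tumor purity") +
    ggplot2::theme_minimal()
}

#' Importance-score decay plot
#'
#' Mean importance score against rank, highlighting genes eligible in all
#' models — the usual way to see how sharply predictive signal concentrates
#' in a few stromal genes.
#'
#' @param object an `importance_table`.
#' @param top_n label the first `top_n` genes (0 = none).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot importance_table
#' @export
autoplot.importance_table <- function(object, top_n = 10, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(dplyr::desc(.data$mean_score)) |>
    dplyr::mutate(index = dplyr::row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$mean_score,
                                        colour = .data$eligible)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey60")) +
    ggplot2::labs(x = "Gene index (by mean importance)",
                  y = "Mean normalized importance",
                  colour = "Non-zero in\nall models") +
    ggplot2::theme_minimal()
  if (top_n > 0) {
    lab <- df[seq_len(min(top_n, nrow(df))), ]
    p <- p + ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$gene),
                                size = 2.5, hjust = -0.1, vjust = 0.5,
                                show.legend = FALSE)
  }
  p
}

#' Permutation null distribution plot
#'
#' @param object a `permutation_result`.
#' @param ... unused.
#' @return A ggplot: histogram of the null statistics with the observed
#'   value marked.
#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = max(10, ceiling(object$B / 4)),
                            fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = paste0("Permutation ", object$statistic),
                  y = "Count",
                  subtitle = sprintf("observed = %.3f, p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
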