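# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy alignment_model
#' @export
tidy.alignment_model <- function(x, ...) x$history

#' @method glance alignment_model
#' @export
glance.alignment_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(epochs = nrow(x$history), subspace_dim = x$config$subspace_dim,
                 L_cls = last$L_cls, L_center = last$L_center,
                 L_domain = last$L_domain, L_consist = last$L_consist,
                 L_total = last$L_total)
}

#' @method tidy flow_model
#' @export
tidy.flow_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), loss = x$history)
}

#' @method glance flow_model
#' @export
glance.flow_model <- function(x, ...) {
  tibble::tibble(epochs = length(x$history), state_dim = x$config$state_dim,
                 cond_dim = x$config$cond_dim, steps = x$config$steps,
                 final_loss = utils::tail(x$history, 1))
}

#' @method tidy flowfuse_mae
#' @export
tidy.flowfuse_mae <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), val_loss = x$history)
}

#' @method glance flowfuse_mae
#' @export
glance.flowfuse_mae <- function(x, ...) {
  tibble::tibble(stop_epoch = x$stop_epoch, best_val_loss = x$best_val_loss,
                 latent_dim = x$config$latent_dim,
                 mask_ratio = x$config$mask_ratio)
}

#' @method tidy flowfuse_pca
#' @export
tidy.flowfuse_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained),
                 explained = x$explained,
                 cumulative = cumsum(x$explained),
                 retained = seq_along(x$explained) <= x$k)
}

#' @method glance flowfuse_pca
#' @export
glance.flowfuse_pca <- function(x, ...) {
  tibble::tibble(k = x$k, threshold = x$threshold,
                 input_dim = length(x$feature_names))
}

#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 macro_sensitivity = x$macro_sensitivity,
                 macro_precision = x$macro_precision,
                 macro_f1 = x$macro_f1, macro_auc = x$macro_auc)
}

#' @method tidy fusion_model
#' @export
tidy.fusion_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history), val_loss = x$history)
}

#' @method glance fusion_model
#' @export
glance.fusion_model <- function(x, ...) {
  tibble::tibble(stop_epoch = x$stop_epoch, best_val_loss = x$best_val_loss,
                 concat_width = x$concat_width, use_se = x$use_se)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$per_seed

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tidyr::pivot_wider(x$aggregate, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Loss-history plot for trained models
#'
#' @param object An `alignment_model`, `flow_model`, `flowfuse_mae` or
#'   `fusion_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot alignment_model
#' @export
autoplot.alignment_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            cols = dplyr::starts_with("L_"),
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Alignment training losses") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.alignment_model
#' @method autoplot flow_model
#' @export
autoplot.flow_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "flow-matching loss",
                  title = "Rectified-flow training") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$n, 1))) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Confusion matrix (accuracy %.3f)",
                                  object$accuracy)) +
    ggplot2::theme_minimal()
}

#' First-two-PC scatter of a synthetic cohort
#'
#' @param object A `synthetic_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_cohort
#' @export
autoplot.synthetic_cohort <- function(object, ...) {
  pc <- pca_fit(object$speech, threshold = 1)
  sc <- predict(pc, object$speech, k = 2)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = "Speech features: first two principal components") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
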