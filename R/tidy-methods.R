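#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the coefficients of a fitted maximum-entropy model
#'
#' @param x a `maxent_model`.
#' @param ... unused.
#' @return A tibble with one row per feature: `feature`, `kind`,
#'   `variable`, `estimate` (the L1-penalised weight), `penalty` (beta),
#'   and `gain_credit` (penalised-gain increase credited to the feature
#'   during fitting).
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  kind <- if (!is.null(x$feature_set)) x$feature_set$defs$kind
          else rep("linear", length(x$lambda))
  variable <- if (!is.null(x$feature_set)) x$feature_set$defs$var1
              else names(x$lambda)
  tibble::tibble(
    feature = names(x$lambda), kind = kind, variable = variable,
    estimate = unname(x$lambda), penalty = unname(x$beta),
    gain_credit = unname(x$contrib)
  )
}

#' One-row summary of a fitted maximum-entropy model
#'
#' @param x a `maxent_model`.
#' @param ... unused.
#' @return A one-row tibble: `n_presence`, `n_background`, `n_features`,
#'   `n_active`, `gain`, `entropy`, `logZ`, `iterations`, `converged`.
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    n_presence = x$meta$n_presence,
    n_background = x$meta$n_background,
    n_features = length(x$lambda),
    n_active = sum(x$lambda != 0),
    gain = x$gain,
    entropy = x$entropy,
    logZ = x$logZ,
    iterations = x$meta$iterations,
    converged = x$meta$converged
  )
}

#' Variable importance plot for a fitted model
#'
#' Bar chart of percent contribution per variable.
#'
#' @param object a `maxent_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot maxent_model
#' @export
autoplot.maxent_model <- function(object, ...) {
  pc <- percent_contribution(object)
  df <- tibble::tibble(variable = names(pc), contribution = unname(pc))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$variable,
                                                      .data$contribution),
                                   y = .data$contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Model contribution (%)") +
    ggplot2::theme_minimal()
}
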