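#' @export
print.gpgee <- function(x, ...) {
  cat("<gpgee> group-penalized GEE fit\n")
  cat("  subjects:", x$n_subjects, " grid:", x$J, "conditions x", x$K,
      "channels\n")
  cat("  correlation:", if (!is.null(x$correlation)) x$correlation$spec$kind
      else x$corstr$kind, "\n")
  cat("  lambda (BIC):", format(x$lambda, digits = 4),
      " selected groups:", length(x$selected_groups), "of",
      length(x$groups$groups), "\n")
  cat("  converged:", x$converged, "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Tidy a GPGEE fit
#'
#' One row per model coefficient with its penalty-group id (`NA` for
#' unpenalized terms) and whether its group was retained.
#'
#' @param x A `gpgee` fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `group`, `penalized`,
#'   `selected`.
#' @export
tidy.gpgee <- function(x, ...) {
  gid <- x$groups$gid
  terms <- if (!is.null(x$terms)) x$terms else paste0("x", seq_len(x$p))
  tibble::tibble(
    term = terms,
    estimate = unname(x$beta),
    group = ifelse(gid == 0L, NA_integer_, gid),
    penalized = gid != 0L,
    selected = x$beta != 0 | gid == 0L
  )
}

#' One-row summary of a GPGEE fit
#'
#' @param x A `gpgee` fit.
#' @param ... Unused.
#' @return A tibble with the chosen penalty, its BIC and degrees of freedom,
#'   counts of selected groups/coefficients, and convergence diagnostics.
#' @export
glance.gpgee <- function(x, ...) {
  best <- which(x$bic_path$lambda == x$lambda)[1]
  tibble::tibble(
    lambda = x$lambda,
    bic = x$bic_path$bic[best],
    df = x$bic_path$df[best],
    n_groups_selected = length(x$selected_groups),
    n_selected = sum(x$beta != 0),
    rss = x$rss,
    iterations = as.integer(x$iterations),
    converged = x$converged,
    n_subjects = x$n_subjects,
    n_obs = x$n_subjects * x$J * x$K
  )
}

#' Plot the BIC tuning path of a GPGEE fit
#'
#' BIC against the penalty level (log scale), with the selected value marked.
#'
#' @param object A `gpgee` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gpgee <- function(object, ...) {
  pd <- object$bic_path[object$bic_path$ok, ]
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$lambda, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "BIC",
                  title = "GPGEE penalty tuning path") +
    ggplot2::theme_minimal()
}

#' Plot selection-category rates from a simulation summary
#'
#' Stacked bar chart of exact/over/under-selection percentages per model row.
#'
#' @param object A tibble from [summarize_replicates()] or [run_table1()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_selection_rates <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object,
    cols = c("pct_over", "pct_under", "pct_exact"),
    names_to = "category", values_to = "pct", names_prefix = "pct_"
  )
  long$row <- interaction(long$model, long$n, sep = ", n=")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$row, y = .data$pct,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of replicates", fill = NULL,
                  title = "Selection outcomes by model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
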