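# ggplot2 visual summaries

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` (see [kaplan_meier()]).
#' @param ... Unused.
#' @return A ggplot step plot of the survival function.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- rbind(tibble::tibble(time = 0, survival = 1),
              tibble::tibble(time = object$time, survival = object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation surface
#'
#' One CVPL curve per repeat on log-lambda, with the selected lambda
#' marked.
#'
#' @param object A `cv_lambda` (see [select_lambda()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_lambda <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = log(.data$lambda), y = .data$cvpl,
                               group = .data$repeat_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = log(object$lambda_hat),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "cross-validated partial likelihood") +
    ggplot2::theme_minimal()
}

#' Plot high/low-risk Kaplan-Meier curves for a validated split
#'
#' @param surv A `survival_data` tibble.
#' @param groups Two-level group labels aligned with `surv` (e.g. the
#'   `group` column returned by [evaluate_testset()]).
#' @return A ggplot object with one step curve per risk group.
#' @export
plot_risk_groups <- function(surv, groups) {
  stopifnot(length(groups) == nrow(surv))
  dfs <- lapply(split(seq_len(nrow(surv)), groups), function(idx) {
    km <- kaplan_meier(surv[idx, , drop = FALSE])
    tibble::tibble(time = c(0, km$time), survival = c(1, km$survival))
  })
  df <- dplyr::bind_rows(dfs, .id = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}
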