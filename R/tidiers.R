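#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an identified transfer-function model
#'
#' @param x A `tf_model`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term` (`b0`..`b5`,
#'   `a1`..`a5`), `estimate`.
#' @method tidy tf_model
#' @export
tidy.tf_model <- function(x, ...) {
  tibble(term = c(paste0("b", seq_along(x$b) - 1),
                  paste0("a", seq_along(x$a[-1]))),
         estimate = c(x$b, x$a[-1]))
}

#' @rdname tidy.tf_model
#' @return For `glance()`: a one-row tibble with `order`, `delay_ms`,
#'   `vaf`, `residual_variance`, `iterations`, `converged`, `stable`.
#' @method glance tf_model
#' @export
glance.tf_model <- function(x, ...) {
  tibble(order = x$order, delay_ms = x$delay_ms, vaf = x$vaf,
         residual_variance = x$residual_variance,
         iterations = x$iterations, converged = x$converged,
         stable = all(Mod(tf_poles(x)) < 1))
}

#' Tidy a cohort analysis report
#'
#' @param x A `csfpulse_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-subject metrics tibble.
#' @method tidy csfpulse_report
#' @export
tidy.csfpulse_report <- function(x, ...) x$subjects

#' @rdname tidy.csfpulse_report
#' @return For `glance()`: one row per group and compartment with the mean
#'   delay and the group crossover frequency.
#' @method glance csfpulse_report
#' @export
glance.csfpulse_report <- function(x, ...) {
  dplyr::left_join(x$group_delays, x$group_crossover,
                   by = c("group", "compartment"))
}
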