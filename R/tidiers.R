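#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-time switching posterior of an E-step
#'
#' One row per time point and candidate model, with the responsibility
#' `h` and the log-evidence `g`.
#'
#' @param x A `vb_estep`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `model`, `h`, `g`.
#' @export
tidy.vb_estep <- function(x, ...) {
  T_ <- nrow(x$h); M <- ncol(x$h)
  tibble::tibble(
    time = rep(seq_len(T_), M),
    model = rep(seq_len(M), each = T_),
    h = as.vector(x$h),
    g = as.vector(x$g))
}

#' @rdname tidy.vb_estep
#' @export
glance.vb_estep <- function(x, ...) {
  tibble::tibble(free_energy = x$free_energy, n_iter = x$n_iter,
                 converged = x$converged, n_models = ncol(x$h),
                 n_obs = nrow(x$h))
}

#' Tidy fitted switching-model parameters
#'
#' One row per scalar parameter of every candidate model and the chain.
#'
#' @param x A `vbem_fit`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `parameter`, `row`, `col`,
#'   `estimate`.
#' @export
tidy.vbem_fit <- function(x, ...) {
  mats <- function(m, name, A) {
    A <- rbind(A)
    tibble::tibble(model = m, parameter = name,
                   row = as.vector(row(A)), col = as.vector(col(A)),
                   estimate = as.vector(A))
  }
  rows <- list()
  for (m in seq_len(x$model$M)) {
    s <- x$model$ssms[[m]]
    rows <- c(rows, list(mats(m, "F", s$F), mats(m, "Q", s$Q),
                         mats(m, "mu", matrix(s$mu, ncol = 1)),
                         mats(m, "Q0", s$Q0)))
  }
  rows <- c(rows, list(mats(NA_integer_, "R", x$model$R),
                       mats(NA_integer_, "phi", x$model$chain$phi),
                       mats(NA_integer_, "rho", matrix(x$model$chain$rho,
                                                       ncol = 1))))
  dplyr::bind_rows(rows)
}

#' @rdname tidy.vbem_fit
#' @export
glance.vbem_fit <- function(x, ...) {
  tibble::tibble(free_energy = x$f_trace[length(x$f_trace)],
                 n_em_iter = x$n_iter, converged = x$converged,
                 n_models = x$model$M)
}

#' @export
tidy.spindle_detection <- function(x, ...) x$events

#' @export
glance.spindle_detection <- function(x, ...) {
  tibble::tibble(n_events = nrow(x$events),
                 center_freq_hz = x$model$ssms[[1]]$blocks[[2]]$omega *
                   x$fs / (2 * pi),
                 total_spindle_s = sum(x$events$offset_s - x$events$onset_s),
                 converged = x$fit$converged)
}

#' Plot the switching posterior over time
#'
#' Responsibility traces for every candidate model.
#'
#' @param object A `vb_estep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vb_estep <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$h,
                                   colour = factor(.data$model))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "time", y = "model responsibility h",
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot spindle detection results
#'
#' Posterior spindle probability with detected events shaded.
#'
#' @param object A `spindle_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spindle_detection <- function(object, ...) {
  p <- ggplot2::ggplot(object$probs,
                       ggplot2::aes(x = .data$time_s, y = .data$prob_spindle)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "P(spindle)") +
    ggplot2::theme_minimal()
  if (nrow(object$events)) {
    p <- p + ggplot2::geom_rect(
      data = object$events, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = 0, ymax = 1),
      fill = "tomato", alpha = 0.2)
  }
  p
}

#' Plot benchmark accuracy distributions
#'
#' Histograms of per-sequence segmentation accuracy by method.
#'
#' @param data A benchmark tibble from [run_benchmark()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(data, bins = 30) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "segmentation accuracy", y = "count") +
    ggplot2::theme_minimal()
}
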