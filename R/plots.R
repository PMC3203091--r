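#' Histograms of the estimates across a power study
#'
#' One panel per estimated parameter and per true hybridization level,
#' mirroring how simulation results for this model are usually displayed:
#' rows are the true `gamma` levels, columns the parameters.
#'
#' @param object A `hyb_power_study`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.hyb_power_study <- function(object, bins = 20, ...) {
  long <- tidyr::pivot_longer(
    object$results,
    cols = c("gamma_hat", "t1_hat", "t2_hat", "t3_hat"),
    names_to = "parameter", values_to = "estimate"
  )
  long$parameter <- factor(long$parameter,
                           levels = c("gamma_hat", "t1_hat", "t2_hat", "t3_hat"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$gamma_true),
      cols = ggplot2::vars(.data$parameter),
      scales = "free",
      labeller = ggplot2::labeller(
        gamma_true = function(x) paste0("true gamma = ", x))
    ) +
    ggplot2::labs(x = "maximum-likelihood estimate", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Optimization trace of a mixture-model fit
#'
#' Shows the log-likelihood and each parameter against the coordinate
#' cycle, which makes non-convergence or boundary attraction easy to spot.
#'
#' @param object A `hyb_fit`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.hyb_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, cols = -"cycle",
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity,
                          levels = c("lnL", "gamma", "t1", "t2", "t3"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(x = "coordinate cycle", y = NULL) +
    ggplot2::theme_minimal()
}

#' One-parameter likelihood profiles around a fit
#'
#' Recomputes the log-likelihood along a grid for each parameter with the
#' other parameters held at their estimates. The flattening of the profile
#' for interval parameters as they grow (and hence their attraction to the
#' upper bound) is the signature behaviour to look for.
#'
#' @param trees,S,map The data and model the fit was produced from.
#' @param fit A `hyb_fit`.
#' @param n_grid Grid points per parameter.
#' @return A tibble with columns `parameter`, `value`, `lnL`; plot it with
#'   `ggplot2` or inspect directly.
#' @export
likelihood_profiles <- function(trees, S, map, fit, n_grid = 41) {
  eval_fn <- .prep_likelihood(trees, S, map,
                              max_resolutions = fit$config$max_resolutions)
  cfg <- fit$config
  grids <- list(
    gamma = seq(cfg$gamma_bounds[1], cfg$gamma_bounds[2], length.out = n_grid),
    t1 = seq(cfg$t_lower, cfg$t_upper, length.out = n_grid),
    t2 = seq(cfg$t_lower, cfg$t_upper, length.out = n_grid),
    t3 = seq(cfg$t_lower, cfg$t_upper, length.out = n_grid)
  )
  p0 <- c(fit$gamma, fit$t)
  purrr::map_dfr(seq_along(grids), function(k) {
    tibble::tibble(
      parameter = names(grids)[k],
      value = grids[[k]],
      lnL = vapply(grids[[k]], function(x) {
        p <- p0
        p[k] <- x
        eval_fn(p[1], p[2:4])
      }, 0)
    )
  })
}
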