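#' Plot the fitted response-response relationship
#'
#' Observed downstream incidences against the log upstream group level
#' (posterior mean of the latent `M_j`), overlaid with the posterior mean
#' curve and a 95% credible ribbon of the chemical-agnostic
#' response-response relationship.
#'
#' @param object A `qaop_fit`.
#' @param n_grid Grid resolution of the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qaop_fit <- function(object, n_grid = 100, ...) {
  sp <- object$model$spec
  d <- object$draws
  down <- which(sp$has_down == 1)
  M_mean <- vapply(down, function(j) mean(d[[paste0("M[", j, "]")]]),
                   numeric(1))
  pts <- tibble::tibble(
    M = M_mean,
    incidence = sp$X[down] / sp$n2[down],
    chemical = object$model$chemicals[sp$chem[down] + 1L]
  )
  grid <- seq(min(pts$M) - 0.5, max(pts$M) + 0.5, length.out = n_grid)
  if (object$model$structure == "hierarchical") {
    v <- d$mu_v; q <- d$mu_q; h <- d$mu_h; r <- d$r
  } else {
    v <- d$v; q <- d$q; h <- d$h; r <- d$r
  }
  curve <- purrr::map_dfr(grid, function(m) {
    s <- stats::plogis(r * (m - h))
    p <- v * (q + (1 - q) * s)
    tibble::tibble(M = m, mean = mean(p),
                   lo = stats::quantile(p, 0.025),
                   hi = stats::quantile(p, 0.975))
  })
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$M)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$incidence,
                                     color = .data$chemical)) +
    ggplot2::labs(x = "log upstream level (latent group mean)",
                  y = "downstream incidence",
                  title = paste(object$model$structure,
                                "response-response fit")) +
    ggplot2::theme_minimal()
}

#' Plot a simulated multi-chemical dataset
#'
#' Downstream incidence against log upstream group mean, colored by
#' chemical, with the true chemical-specific response-response curves.
#'
#' @param object A `simulated_qaop` dataset from [generate_qaop_data()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simulated_qaop <- function(object, ...) {
  truth <- attr(object, "truth")
  pts <- tibble::tibble(
    M = truth$M,
    incidence = object$ke_down_cases / object$ke_down_n,
    chemical = object$chemical_id
  )
  grid <- seq(min(pts$M) - 0.5, max(pts$M) + 0.5, length.out = 80)
  curves <- purrr::map_dfr(seq_len(nrow(truth$theta2)), function(k) {
    pr <- truth$theta2[k, ]
    tibble::tibble(
      chemical = sprintf("chem%02d", k), M = grid,
      p = hill_dichotomous(grid, list(v = pr$v, q = pr$q, h = pr$h,
                                      r = truth$config$r))
    )
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$M, y = .data$p,
                               color = .data$chemical)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(data = pts, ggplot2::aes(y = .data$incidence)) +
    ggplot2::labs(x = "log upstream level", y = "downstream probability",
                  title = sprintf("simulated data, Cohen's f = %.2f",
                                  truth$achieved_f)) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison
#'
#' Bar chart of the hierarchical-minus-flat elpd differences with +/- 1 SE
#' error bars, per metric.
#'
#' @param object A `qaop_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qaop_comparison <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$method, y = .data$diff)) +
    ggplot2::geom_col(width = 0.5, fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$diff - .data$diff_se,
                                        ymax = .data$diff + .data$diff_se),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "elpd difference (hierarchical - flat)", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark-level posterior
#'
#' Histogram of the posterior BML draws (natural scale) with the BML,
#' BMLL and BMLU marked.
#'
#' @param object A `bml_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bml_result <- function(object, ...) {
  marks <- tibble::tibble(
    what = c("BMLL", "BML", "BMLU"),
    value = unname(object$natural[c("BMLL", "BML", "BMLU")])
  )
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$bml)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$value,
                                     linetype = .data$what)) +
    ggplot2::labs(x = "benchmark level (natural upstream scale)",
                  y = "posterior draws") +
    ggplot2::theme_minimal()
}
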