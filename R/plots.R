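#' Plot a trait-modulated environmental response profile
#'
#' The centred response line with its confidence band, plus the
#' per-species estimated environmental responses positioned at their
#' standardized trait values. Species above zero respond positively to
#' the environmental variable.
#'
#' @param object A `te_profile` from [trait_response_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_profile <- function(object, ...) {
  tl <- te_trait_labels(); el <- te_env_labels()
  ggplot2::ggplot(object$line, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(
      data = object$species,
      ggplot2::aes(x = .data$trait_value, y = .data$response)
    ) +
    ggplot2::labs(
      x = paste0(tl[object$trait], " (standardized)"),
      y = paste0("Centred response to ", tolower(el[object$environment])),
      title = sprintf("%s (coef %.2f, SE %.2f)", object$term,
                      object$coefficient, object$se)
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a fitted occurrence model
#'
#' Point estimates with 95% Wald intervals for all fixed effects, in
#' reporting order.
#'
#' @param object A `te_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_fit <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = "Coefficient (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Grid of all trait-by-environment response panels
#'
#' One [trait_response_profile()] panel for each of the 12 trait x
#' environment pairs, faceted traits-by-environments.
#'
#' @param fit A `te_fit`.
#' @return A ggplot object.
#' @export
plot_trait_env_grid <- function(fit) {
  stopifnot(inherits(fit, "te_fit"))
  tl <- te_trait_labels(); el <- te_env_labels()
  panels <- purrr::map(seq_len(nrow(fit$design$interactions)), function(i) {
    pr <- trait_response_profile(
      fit, fit$design$interactions$trait[i],
      fit$design$interactions$environment[i]
    )
    list(
      line = pr$line %>% mutate(term = pr$term),
      species = pr$species %>% mutate(term = pr$term)
    )
  })
  lines <- purrr::list_rbind(purrr::map(panels, "line")) %>%
    mutate(term = factor(.data$term, levels = fit$design$interactions$term))
  pts <- purrr::list_rbind(purrr::map(panels, "species")) %>%
    mutate(term = factor(.data$term, levels = fit$design$interactions$term))
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$response)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$trait_value, y = .data$response), size = 0.8
    ) +
    ggplot2::facet_wrap(~term, ncol = 3, scales = "free_x") +
    ggplot2::labs(x = "Standardized trait value",
                  y = "Centred environmental response") +
    ggplot2::theme_minimal()
}
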