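# Mean-score profile plot (one panel per profile, one line per informant).

#' Plot profile mean scores per informant and scale
#'
#' One panel per latent profile, subscale means on the y axis, with one line
#' per informant; panel titles carry the profile labels when available.
#'
#' @param x an `sdqmix_profiles` object (from [profile_summary()]) or a
#'   data.frame of class means as produced by [class_means()].
#' @param drop_total drop the derived `total_difficulties` rows (default
#'   TRUE; they live on a different scale than the subscales).
#' @return A ggplot object.
#' @export
plot_profiles <- function(x, drop_total = TRUE) {
  if (inherits(x, "sdqmix_profiles")) {
    means <- x$means
    means$panel <- sprintf("%d: %s", means$class, x$labels[as.character(means$class)])
  } else {
    means <- x
    means$panel <- sprintf("profile %d", means$class)
  }
  if (drop_total) means <- means[means$scale != "total_difficulties", ]
  means$scale <- factor(means$scale, levels = unique(means$scale))
  ggplot2::ggplot(means, ggplot2::aes(x = scale, y = mean,
                                      colour = informant,
                                      group = informant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = "mean subscale score", colour = "informant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
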