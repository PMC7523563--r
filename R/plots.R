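#' Plot a fitted cline over the observed frequencies
#'
#' @param object A [fit_cline()] result.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cline_fit
#' @export
autoplot.cline_fit <- function(object, n_grid = 400, ...) {
  d <- object$data
  xr <- range(d$distance_km)
  grid <- tibble(
    distance_km = seq(xr[1], xr[2], length.out = n_grid)
  ) %>%
    mutate(frequency = cline_value(.data$distance_km, object$model))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance_km, y = .data$frequency)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_alleles), alpha = 0.7) +
    ggplot2::geom_line(data = grid, linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$estimates[["center"]],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(
      x = "Transect distance (km)", y = "Focal-allele frequency",
      size = "Alleles",
      title = sprintf("Cline fit (tails = %s): c = %.1f km, w = %.1f km",
                      object$tails, object$estimates[["center"]],
                      object$estimates[["width"]])
    ) +
    ggplot2::theme_minimal()
}

#' Triangle plot of interspecific heterozygosity against hybrid index
#'
#' F1 hybrids sit at the apex (q = 0.5, het = 1); parentals at the base
#' corners; backcrosses along the sides.
#'
#' @param admixture A [hybrid_index()] tibble.
#' @return A ggplot.
#' @export
plot_triangle <- function(admixture) {
  edge <- tibble(
    q = c(0, 0.5, 1),
    het = c(0, 1, 0)
  )
  ggplot2::ggplot(admixture,
                  ggplot2::aes(x = .data$hybrid_index_q,
                               y = .data$interspecific_het)) +
    ggplot2::geom_path(data = edge, ggplot2::aes(x = .data$q, y = .data$het),
                       linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Hybrid index (q)", y = "Interspecific heterozygosity") +
    ggplot2::theme_minimal()
}

#' Tile plot of the tag presence distribution
#'
#' @param dist A [radsex_distribution()] tibble.
#' @return A ggplot.
#' @export
plot_radsex_distribution <- function(dist) {
  ggplot2::ggplot(
    dist %>% mutate(n_tags = ifelse(.data$n_tags == 0, NA_integer_, .data$n_tags)),
    ggplot2::aes(x = .data$n_males, y = .data$n_females, fill = log10(.data$n_tags))
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "Males with tag", y = "Females with tag",
                  fill = "log10 tags") +
    ggplot2::theme_minimal()
}

#' Transect profiles of admixture statistics
#'
#' Mean hybrid index, observed heterozygosity and admixture LD against
#' transect distance; the latter two peak at the cline center.
#'
#' @param summaries A [population_summaries()] tibble.
#' @return A ggplot.
#' @export
plot_zone_summaries <- function(summaries) {
  long <- summaries %>%
    select("population_id", "distance_km", "mean_q", "Ho",
           "admix_ld_Dprime") %>%
    tidyr::pivot_longer(c("mean_q", "Ho", "admix_ld_Dprime"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance_km, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Transect distance (km)", y = NULL) +
    ggplot2::theme_minimal()
}
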