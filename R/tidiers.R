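# Broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @method tidy correlation_map
#' @export
tidy.correlation_map <- function(x, ...) {
  genes <- x$genes
  if (length(genes) < 2) {
    return(tibble::tibble(gene_1 = character(), gene_2 = character(),
                          r = numeric()))
  }
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(gene_1 = genes[idx[, 1]], gene_2 = genes[idx[, 2]],
                 r = x$r[idx])
}

#' @method tidy hub_call
#' @export
tidy.hub_call <- function(x, ...) {
  tibble::tibble(gene = names(x$dc), dc = unname(x$dc),
                 is_hub = names(x$dc) %in% x$hubs) |>
    dplyr::arrange(dplyr::desc(.data$dc), .data$gene)
}

#' @method glance hub_call
#' @export
glance.hub_call <- function(x, ...) {
  dplyr::mutate(x$cutoff, n_hubs = length(x$hubs))
}

#' @method tidy hbs_report
#' @export
tidy.hbs_report <- function(x, ...) {
  tibble::tibble(gene = x$union,
                 hub = x$union %in% x$hubs,
                 bottleneck = x$union %in% x$bottlenecks,
                 ssg = x$union %in% x$ssgs)
}

#' @method glance hbs_report
#' @export
glance.hbs_report <- function(x, ...) {
  dplyr::mutate(x$overlaps, union_size = length(x$union))
}

#' @method tidy sspin_run
#' @export
tidy.sspin_run <- function(x, ...) {
  x$stages$prioritization
}

#' @method glance sspin_run
#' @export
glance.sspin_run <- function(x, ...) {
  x$summary
}

#' Plot a disease-versus-control co-expression contrast
#'
#' Scatter of each pair's control correlation against its disease
#' correlation; pairs on the diagonal co-express equally in both conditions,
#' pairs far below it are disease-specific.
#'
#' @param object A `coexpr_contrast` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot coexpr_contrast
#' @export
autoplot.coexpr_contrast <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$r_control, y = .data$r_disease)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Pearson r (control)", y = "Pearson r (disease)",
                  title = "Differential co-expression contrast") +
    ggplot2::theme_minimal()
}

#' Plot candidate connectivity from a prioritization
#'
#' Bar chart of co-expression connectivity per candidate, coloured by
#' selection status, with the selection threshold drawn.
#'
#' @param object A `prioritization` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot prioritization
#' @export
autoplot.prioritization <- function(object, ...) {
  df <- dplyr::mutate(object,
                      gene = factor(.data$gene, levels = rev(.data$gene)))
  cut <- attr(object, "min_connectivity") %||% NA_real_
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$connectivity, y = .data$gene,
                                        fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70")) +
    ggplot2::labs(x = "Co-expression partners", y = NULL, fill = "Selected",
                  title = "Candidate prioritization by connectivity") +
    ggplot2::theme_minimal()
  if (is.finite(cut)) {
    p <- p + ggplot2::geom_vline(xintercept = cut - 0.5, linetype = "dotted")
  }
  p
}

#' Plot degree against betweenness with hub / bottleneck calls
#'
#' @param centrality A [centrality_table()] tibble.
#' @param hub_call Optional `hub_call` to draw the degree cutoff.
#' @param bottlenecks Optional character vector to highlight bottlenecks.
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality, hub_call = NULL, bottlenecks = NULL) {
  df <- dplyr::mutate(
    centrality,
    class = dplyr::case_when(
      !is.null(hub_call) & .data$gene %in% (hub_call$hubs %||% character()) &
        .data$gene %in% (bottlenecks %||% character()) ~ "hub + bottleneck",
      !is.null(hub_call) & .data$gene %in% (hub_call$hubs %||% character()) ~ "hub",
      .data$gene %in% (bottlenecks %||% character()) ~ "bottleneck",
      TRUE ~ "other"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dc, y = .data$bc,
                                        colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Degree centrality", y = "Normalized betweenness",
                  colour = NULL, title = "Network centrality map") +
    ggplot2::theme_minimal()
  if (!is.null(hub_call)) {
    p <- p + ggplot2::geom_vline(xintercept = hub_call$cutoff$cutoff,
                                 linetype = "dashed")
  }
  p
}
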