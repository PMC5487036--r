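# ggplot2 displays for metric series and screening reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metric time series
#'
#' @param object A `cna_series` (e.g. from [core_rmsd_series()] or
#'   [lj_energy_series()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cna_series <- function(object, ...) {
  df <- tibble::as_tibble(object)
  xvar <- if ("time" %in% names(df) && !all(is.na(df$time))) "time" else "frame"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$value)) +
    ggplot2::geom_line(colour = "#5e3c99") +
    ggplot2::geom_hline(yintercept = mean(df$value), linetype = 2,
                        colour = "grey40") +
    ggplot2::labs(x = if (xvar == "time") "time (ns)" else "frame",
                  y = paste0(attr(object, "label"), " (",
                             attr(object, "unit"), ")")) +
    ggplot2::theme_minimal()
}

#' Domain-vs-split comparison plot for a screening report
#'
#' Side-by-side mean core RMSD and tag vdW energy for every screened
#' system.
#'
#' @param object A `cna_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cna_screen <- function(object, ...) {
  tb <- tidy(object)
  long <- tb |>
    dplyr::select("system", "rmsd_domain", "rmsd_split", "lj_domain",
                  "lj_split") |>
    tidyr::pivot_longer(-"system", names_to = c("metric", "variant"),
                        names_sep = "_") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         rmsd = "core RMSD (A)",
                                         lj = "tag vdW energy (kcal/mol)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$system, y = .data$value,
                                     fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(domain = "#5e3c99",
                                          split = "#e66101")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-pair hydrogen-bond mean distances
#'
#' @param means_domain,means_split Outputs of [hbond_means()] for the
#'   intact domain and the split system.
#' @return A ggplot object.
#' @export
plot_hbond_means <- function(means_domain, means_split = NULL) {
  df <- dplyr::bind_rows(
    dplyr::mutate(means_domain, variant = "domain"),
    if (!is.null(means_split)) dplyr::mutate(means_split,
                                             variant = "split"))
  df$pair <- paste0(df$donor_res, "→", df$acceptor_res)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$mean_distance,
                                   fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 3.5, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(domain = "#5e3c99",
                                          split = "#e66101")) +
    ggplot2::labs(x = "backbone N→O pair",
                  y = "mean N···O distance (Å)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
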