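#' Plot per-candidate selection criteria
#'
#' Side-by-side ACE and AICc values for each candidate, with the selected
#' model highlighted. Both criteria are "smaller is better"; they are on
#' different scales, so panels are free.
#'
#' @param object A `selection_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_report <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("ace", "aicc"), names_to = "criterion",
                        values_to = "value") |>
    mutate(
      criterion = toupper(.data$criterion),
      selected = (.data$criterion == "ACE" &
                    .data$candidate == object$selected_by_ace) |
        (.data$criterion == "AICC" &
           .data$candidate == object$selected_by_aicc)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate, y = .data$value,
                                   fill = .data$selected)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = "criterion value (smaller is better)") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap model-selection probabilities
#'
#' @param object A `bootstrap_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_summary <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("p_ace", "p_aicc"), names_to = "criterion",
                        values_to = "probability") |>
    mutate(criterion = ifelse(.data$criterion == "p_ace", "ACE", "AICc"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate,
                                   y = .data$probability,
                                   fill = .data$criterion)) +
    ggplot2::geom_col(position = "dodge", width = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "selection probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Marginal snapshot distributions at two times
#'
#' Overlays per-protein abundance densities of the time-0 and time-t
#' snapshots -- the raw material the selection method works from.
#'
#' @param t0,yt Snapshots (cells x species).
#' @param time Label for the second snapshot.
#' @return A ggplot object.
#' @export
plot_snapshots <- function(t0, yt, time = attr(yt, "time") %||% "t") {
  df <- dplyr::bind_rows(
    mutate(as_tibble(t0), snapshot = "t = 0"),
    mutate(as_tibble(yt), snapshot = paste0("t = ", time))
  ) |>
    tidyr::pivot_longer(-"snapshot", names_to = "protein",
                        values_to = "abundance")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abundance,
                                   color = .data$snapshot)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~protein, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "abundance (copies, log scale)", y = "density",
                  color = NULL) +
    ggplot2::theme_minimal()
}
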