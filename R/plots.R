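# ggplot2 displays for the main result types.

#' @describeIn icelogo Heat-map display of an IceLogo matrix (frequency, or
#'   log2 fold change when a normalisation was applied).
#' @param object An `icelogo` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.icelogo <- function(object, ...) {
  raw <- attr(object, "normalization") == "raw"
  val <- if (raw) object$frequency else log2(object$fold_change)
  df <- dplyr::mutate(object, value = val)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position_label, levels = unique(.data$position_label)),
    y = .data$residue, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick",
                                  midpoint = if (raw) 0.05 else 0) +
    ggplot2::labs(x = "position", y = "residue",
                  fill = if (raw) "frequency" else "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Plot cumulative k-mer coverage curves
#'
#' @param ... Named [kmer_cdf()] tibbles (one line per set).
#' @return A ggplot.
#' @export
plot_kmer_cdf <- function(...) {
  sets <- list(...)
  df <- purrr::imap_dfr(sets, function(d, nm) dplyr::mutate(d, set = nm))
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$cumulative_fraction,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "unique k-mers (by descending count)",
                  y = "cumulative fraction of occurrences") +
    ggplot2::theme_minimal()
}

#' Efficiency-selectivity quadrant plot
#'
#' @param data Tibble with `efficiency` and `selectivity` columns (and an
#'   optional `group` column for colouring).
#' @param e_cut,s_cut Quadrant cuts drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_quadrants <- function(data, e_cut = 0.4, s_cut = 2.4) {
  aes <- if ("group" %in% names(data)) {
    ggplot2::aes(.data$efficiency, .data$selectivity, colour = .data$group)
  } else {
    ggplot2::aes(.data$efficiency, .data$selectivity)
  }
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = e_cut, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = s_cut, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "cleavage efficiency", y = "selectivity score") +
    ggplot2::theme_minimal()
}

#' @describeIn train_predictor_ensemble Training-history curves for each
#'   ensemble member.
#' @param object A `cleavage_ensemble`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.cleavage_ensemble <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("train_loss", "held_out_loss"),
                        names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = factor(.data$member),
                                   linetype = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(colour = "member") +
    ggplot2::theme_minimal()
}
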