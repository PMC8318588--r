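#' Woods plot of differential uptake along the sequence
#'
#' One horizontal segment per peptide at its uptake difference, with the
#' summed-SEM envelope shown as a ribbon around zero; significantly
#' protected peptides fall below the envelope, significantly exposed ones
#' above it. Faceted by exposure time.
#'
#' @param x An `hdx_protection` object or [differential_uptake()] tibble.
#' @param protein Optional protein id to restrict the plot to.
#' @return A ggplot object.
#' @export
plot_woods <- function(x, protein = NULL) {
  d <- woods_table(x)
  if (!is.null(protein)) d <- dplyr::filter(d, .data$protein_id == protein)
  d$status <- dplyr::case_when(
    d$significant_protection ~ "protected",
    d$significant_exposure ~ "exposed",
    TRUE ~ "not significant"
  )
  ggplot2::ggplot(d) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        x = (.data$start + .data$end) / 2,
        ymin = -.data$envelope, ymax = .data$envelope
      ),
      fill = "grey80", alpha = 0.6
    ) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$delta, yend = .data$delta, colour = .data$status
      ),
      linewidth = 1
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(
      "protected" = "#2166AC", "exposed" = "#B2182B",
      "not significant" = "grey40"
    )) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$exposure_min),
      cols = if (length(unique(d$protein_id)) > 1) ggplot2::vars(.data$protein_id) else NULL,
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "residue position", y = "uptake difference (Da)",
      colour = NULL,
      title = "Differential deuterium uptake (complex - apo)"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot hdx_protection
#' @export
autoplot.hdx_protection <- function(object, ...) plot_woods(object, ...)

#' Butterfly plot of per-position relative uptake in the two states
#'
#' Mirrored per-state relative uptake along the sequence: the first state is
#' drawn upward, the second downward, one line per exposure time.
#'
#' @param x An `hdx_protection` object or [summarize_uptake()] tibble.
#' @param protein Optional protein id to restrict the plot to.
#' @return A ggplot object.
#' @export
plot_butterfly <- function(x, protein = NULL) {
  b <- butterfly_table(x)
  if (!is.null(protein)) b <- dplyr::filter(b, .data$protein_id == protein)
  states <- sort(unique(b$state))
  b$signed <- ifelse(b$state == states[1], 1, -1) * b$relative_uptake
  ggplot2::ggplot(b, ggplot2::aes(
    x = .data$position, y = .data$signed,
    colour = factor(.data$exposure_min)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$protein_id), scales = "free_x") +
    ggplot2::labs(
      x = "residue position",
      y = sprintf("relative uptake (%s up, %s down)", states[1], states[2]),
      colour = "exposure (min)"
    ) +
    ggplot2::theme_minimal()
}

#' Residue-level protection track
#'
#' Bar plot of the number of protected peptides covering each residue, with
#' the called minimal segments underlined.
#'
#' @param x An `hdx_protection` object.
#' @param proteins Protein tibble with lengths (needed for the residue axis).
#' @return A ggplot object.
#' @export
plot_protection_map <- function(x, proteins) {
  stopifnot(inherits(x, "hdx_protection"))
  map <- residue_protection_map(x$protected, proteins)
  p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_col(width = 1, fill = "#2166AC") +
    ggplot2::facet_wrap(ggplot2::vars(.data$protein_id), scales = "free_x") +
    ggplot2::labs(
      x = "residue position", y = "protected peptide depth"
    ) +
    ggplot2::theme_minimal()
  if (nrow(x$segments)) {
    p <- p + ggplot2::geom_segment(
      data = x$segments,
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = -0.3, yend = -0.3
      ),
      linewidth = 2, colour = "#B2182B"
    )
  }
  p
}

#' Sequence-logo style conservation plot
#'
#' Letters stacked per column, scaled so the stack height equals the column
#' information content in bits (a text-based logo rendering; export
#' [logo_matrix()] for dedicated logo software).
#'
#' @param profile Output of [column_profile()].
#' @return A ggplot object.
#' @export
plot_logo <- function(profile) {
  d <- dplyr::filter(profile, !is.na(.data$residue))
  d <- dplyr::mutate(
    dplyr::group_by(
      dplyr::arrange(d, .data$column, .data$frequency),
      .data$column
    ),
    height = .data$frequency * .data$ic,
    ytop = cumsum(.data$height),
    ymid = .data$ytop - .data$height / 2
  )
  d <- dplyr::ungroup(d)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$column, y = .data$ymid, label = .data$residue
  )) +
    ggplot2::geom_text(ggplot2::aes(size = .data$height, colour = .data$residue),
      show.legend = FALSE
    ) +
    ggplot2::scale_size_continuous(range = c(1, 8)) +
    ggplot2::scale_x_continuous(breaks = unique(d$column)) +
    ggplot2::labs(x = "alignment column", y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' Match map for a proteome scan
#'
#' @param object A `motif_scan`.
#' @param ... Unused.
#' @return A ggplot object showing match positions per carrier protein.
#' @method autoplot motif_scan
#' @export
autoplot.motif_scan <- function(object, ...) {
  m <- object$matches
  ggplot2::ggplot(m, ggplot2::aes(
    x = .data$start, y = .data$protein_id
  )) +
    ggplot2::geom_point(shape = 124, size = 4, colour = "#2166AC") +
    ggplot2::labs(
      x = "match start position", y = NULL,
      title = sprintf(
        "%s: %d match(es) in %d protein(s)",
        object$pattern, object$total_matches, object$distinct_proteins
      )
    ) +
    ggplot2::theme_minimal()
}
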