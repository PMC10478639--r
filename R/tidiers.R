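# broom-style tidiers and ggplot2 autoplot methods for mrprep result types.

#' Tidy a domain partition into a per-domain summary
#'
#' @param x A `domain_partition`.
#' @param ... Unused.
#' @return A tibble with one row per domain: `domain`, `size`, `ranges`.
#' @method tidy domain_partition
#' @export
tidy.domain_partition <- function(x, ...) {
  part <- filter(as_tibble(x), !is.na(.data$domain))
  part |>
    group_by(.data$domain) |>
    summarise(size = n(),
              ranges = collapse_ranges(.data$chain, .data$resno),
              .groups = "drop")
}

#' One-row summary of a domain partition
#'
#' @param x A `domain_partition`.
#' @param ... Unused.
#' @return A tibble with `method`, `n_domains`, `n_residues`, `n_removed`.
#' @method glance domain_partition
#' @export
glance.domain_partition <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_domains = n_domains(x),
    n_residues = sum(!is.na(x$domain)),
    n_removed = sum(is.na(x$domain))
  )
}

#' Plot a PAE matrix as a heatmap
#'
#' @param object A [pae_matrix].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pae_matrix
#' @export
autoplot.pae_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(scored = seq_len(nrow(object)),
                           aligned = seq_len(ncol(object)))
  df$pae <- as.vector(t(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aligned, y = .data$scored,
                                   fill = .data$pae)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "PAE (Å)", direction = -1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "aligned residue", y = "scored residue")
}

#' Plot a domain partition along the sequence
#'
#' @param object A `domain_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot domain_partition
#' @export
autoplot.domain_partition <- function(object, ...) {
  df <- as_tibble(object)
  df$domain_f <- factor(ifelse(is.na(df$domain), "removed",
                               paste0("domain ", df$domain)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_index, y = .data$domain_f,
                                   colour = .data$domain_f)) +
    ggplot2::geom_point(shape = 15, size = 2, show.legend = FALSE) +
    ggplot2::labs(x = "residue (file order)", y = NULL,
                  title = sprintf("%s split: %d domain(s)",
                                  attr(object, "method"), n_domains(object)))
}

#' Plot per-residue confidence along the sequence
#'
#' For pLDDT profiles the AlphaFold band boundaries (50/70/90) are drawn.
#'
#' @param model A [predicted_model].
#' @param profile Optional [confidence_profile()].
#' @return A ggplot object.
#' @export
plot_confidence <- function(model, profile = NULL) {
  profile <- profile %||% confidence_profile(model)
  kind <- profile_kind(profile)
  p <- ggplot2::ggplot(as_tibble(profile),
                       ggplot2::aes(x = .data$res_index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue (file order)",
                  y = switch(kind, plddt100 = "pLDDT", plddt1 = "pLDDT (0-1)",
                             rmsd_angstrom = "est. r.m.s.d. (Å)",
                             "B (Å²)"))
  if (kind == "plddt100") {
    p <- p + ggplot2::geom_hline(yintercept = c(50, 70, 90),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
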