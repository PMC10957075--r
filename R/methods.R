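#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a liability profile
#'
#' One row per detected liability with its flags, dropping list-columns.
#'
#' @param x A `liab_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.liab_profile <- function(x, ...) {
  x$hits |>
    dplyr::select(dplyr::any_of(c(
      "unit_id", "chain_id", "chain_type", "motif_tag", "severity",
      "imgt_start", "matched", "attribution", "germline", "therapeutic",
      "surface")))
}

#' @export
glance.liab_profile <- function(x, ...) {
  tibble(
    n_units = nrow(x$units),
    n_chains = length(unique(x$chains$chain_id)),
    n_hits = nrow(x$hits),
    n_high = sum(x$hits$severity == "high"),
    n_medium = sum(x$hits$severity == "medium"),
    n_low = sum(x$hits$severity == "low"),
    flags_applied = paste(x$flags_applied, collapse = "+")
  )
}

#' Tidy a dataset summary
#'
#' Returns the per-combination flag-reduction table.
#'
#' @param x A `liab_summary`.
#' @param ... Unused.
#' @return A tibble with one row per flag combination.
#' @export
tidy.liab_summary <- function(x, ...) x$combos

#' @export
glance.liab_summary <- function(x, ...) x$overview

#' Plot flag-reduction accounting
#'
#' Bar chart of liabilities remaining after each flag combination.
#'
#' @param object A `liab_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.liab_summary <- function(object, ...) {
  d <- object$combos
  d$combo <- factor(d$combo, levels = d$combo)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$combo,
                                  y = .data$remaining_liabilities)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overview$total_liabilities,
                        linetype = "dashed") +
    ggplot2::labs(x = "flag combination", y = "liabilities remaining",
                  title = "Flag-reduction accounting") +
    ggplot2::theme_minimal()
}

#' Plot liability positions along the variable domain
#'
#' Counts of liabilities per IMGT start position, coloured by severity,
#' with CDR spans shaded.
#'
#' @param object A `liab_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.liab_profile <- function(object, ...) {
  h <- object$hits
  h$pos_num <- parse_imgt_label(h$imgt_start)$number
  b <- imgt_region_bounds()
  cdrs <- b[startsWith(b$region, "CDR"), ]
  ggplot2::ggplot(h, ggplot2::aes(x = .data$pos_num,
                                  fill = .data$severity)) +
    ggplot2::geom_rect(data = cdrs,
                       ggplot2::aes(xmin = .data$start - 0.5,
                                    xmax = .data$end + 0.5,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.15) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(values = c(high = "firebrick",
                                          medium = "darkorange",
                                          low = "gold")) +
    ggplot2::labs(x = "IMGT position", y = "liabilities",
                  title = "Liability positions (CDRs shaded)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
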