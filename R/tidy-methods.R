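## broom-style verbs and plotting for call sets and evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a genotype call set
#'
#' Returns the calls as a plain tibble, one row per site, with a `genotype`
#' label (`hom_ref` / `het` / `hom_alt` for diploid calls, `ref` / `alt` for
#' haploid calls).
#'
#' @param x A `markergt_calls` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.markergt_calls <- function(x, ...) {
  out <- tibble::as_tibble(x)
  if (!is.null(attr(x, "ploidy")) && attr(x, "ploidy") == 2L) {
    out$genotype <- c("hom_alt", "het", "hom_ref")[out$g + 1L]
  } else if ("allele" %in% names(out)) {
    out$genotype <- ifelse(out$allele == 0L, "ref", "alt")
  }
  out
}

#' One-row summary of a genotype call set
#'
#' @param x A `markergt_calls` object.
#' @param ... Unused.
#' @return A one-row tibble with site counts, genotype-class counts and mean
#'   evidence depth.
#' @export
glance.markergt_calls <- function(x, ...) {
  d <- tibble::as_tibble(x)
  out <- tibble::tibble(
    n_sites = nrow(d),
    n_with_evidence = sum(d$k > 0),
    mean_depth = mean(d$k))
  if ("g" %in% names(d)) {
    out$n_hom_ref <- sum(d$g == 2L)
    out$n_het <- sum(d$g == 1L)
    out$n_hom_alt <- sum(d$g == 0L)
  } else if ("allele" %in% names(d)) {
    out$n_ref <- sum(d$allele == 0L)
    out$n_alt <- sum(d$allele != 0L)
  }
  out
}

#' Tidy an evaluation report
#' @param x A `markergt_eval` object.
#' @param ... Unused.
#' @return The report as a plain tibble.
#' @export
tidy.markergt_eval <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of an evaluation report (the `All` stratum)
#' @param x A `markergt_eval` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.markergt_eval <- function(x, ...) {
  d <- tibble::as_tibble(x)
  d[d$stratum == "All", c("level", "precision", "recall", "f1")]
}

#' Plot precision/recall/F1 by variant stratum
#'
#' @param object A `markergt_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.markergt_eval <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "variant class", y = NULL,
                  title = paste0("genotyping accuracy (",
                                 object$level[1], " level)")) +
    ggplot2::theme_minimal()
}

#' Plot evidence-depth distribution of a call set
#'
#' @param object A `markergt_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.markergt_calls <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, fill = .data$genotype)) +
    ggplot2::geom_histogram(binwidth = 1, position = "stack") +
    ggplot2::labs(x = "allele observations per site (k)", y = "sites") +
    ggplot2::theme_minimal()
}
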