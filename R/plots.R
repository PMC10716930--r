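# ggplot2 presentations of the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a maximum-similarity histogram
#'
#' @param object A `similarity_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.similarity_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_lo + 0.025, y = .data$count)) +
    ggplot2::geom_col(width = 0.045, fill = "#3182bd") +
    ggplot2::labs(x = "maximum Tanimoto similarity to references",
                  y = "molecules") +
    ggplot2::theme_minimal()
}

#' Plot a QED distribution
#'
#' @param object A `qed_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qed_distribution <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_lo + 0.025, y = .data$count)) +
    ggplot2::geom_col(width = 0.045, fill = "#31a354") +
    ggplot2::labs(x = "QED", y = "molecules") +
    ggplot2::theme_minimal()
}

#' Plot a chemical-space embedding
#'
#' @param object A `chem_embedding`.
#' @param ... Unused.
#' @return A ggplot (references in grey behind queries).
#' @export
autoplot.chem_embedding <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = df[df$set == "reference", ],
      ggplot2::aes(x = .data$x, y = .data$y), colour = "grey75", size = 0.7
    ) +
    ggplot2::geom_point(
      data = df[df$set == "query", ],
      ggplot2::aes(x = .data$x, y = .data$y), colour = "#e6550d", size = 0.9
    ) +
    ggplot2::labs(x = "UMAP component 1", y = "UMAP component 2") +
    ggplot2::theme_minimal()
}

#' Plot replicate generation metrics
#'
#' Bar chart of mean database-match counts per reward condition with
#' standard-deviation error bars across replicates.
#'
#' @param object A `generation_metrics_summary` from
#'   [metrics_replicates()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.generation_metrics_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$condition <- paste0(df$reward, " (C=", df$c_explore, ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$db_matches_mean)) +
    ggplot2::geom_col(fill = "#756bb1") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$db_matches_mean - .data$db_matches_sd,
                   ymax = .data$db_matches_mean + .data$db_matches_sd),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "generated molecules matched to the DB") +
    ggplot2::theme_minimal()
}
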