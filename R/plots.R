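#' Plot methods for scan results
#'
#' `autoplot()` on an `svld_scan` shows every scored candidate pair as a
#' point (distance from the SV span vs g2), with the catalog threshold drawn
#' as a horizontal line and passing pairs highlighted; degenerate pairs are
#' omitted.
#'
#' @param object An `svld_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.svld_scan <- function(object, ...) {
  pairs <- object$pairs[!object$pairs$degenerate, , drop = FALSE]
  pairs$status <- ifelse(pairs$g_squared >= object$config$min_g2,
                         "in catalog", "below threshold")
  ggplot2::ggplot(pairs,
                  ggplot2::aes(x = .data$distance_bp / 1000,
                               y = .data$g_squared,
                               colour = .data$status)) +
    ggplot2::geom_hline(yintercept = object$config$min_g2,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c("in catalog" = "#B2182B",
                                            "below threshold" = "#2166AC")) +
    ggplot2::labs(x = "SNP distance from SV span (kbp)",
                  y = expression(g^2),
                  colour = NULL,
                  title = "Candidate SV-SNP pairs",
                  subtitle = sprintf("catalog threshold g² ≥ %g",
                                     object$config$min_g2)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Stage-attrition funnel of a scan
#'
#' Bar chart of the scan's stage counts: significant associations, matched
#' SNPs, candidate pairs, pairs passing the g2 filter and final catalog
#' rows — the funnel a user audits to see where candidates were lost.
#'
#' @param x An `svld_scan` object.
#' @return A ggplot object.
#' @export
plot_scan_funnel <- function(x) {
  s <- x$summary
  stages <- tibble(
    stage = factor(c("significant\nassociations", "matched\nSNPs",
                     "candidate\npairs", "passing\ng2", "catalog\nrows"),
                   levels = c("significant\nassociations", "matched\nSNPs",
                              "candidate\npairs", "passing\ng2",
                              "catalog\nrows")),
    count = c(s$associations_significant, s$snps_matched, s$candidate_pairs,
              s$pairs_passing, s$catalog_rows))
  ggplot2::ggplot(stages, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "count", title = "Scan attrition") +
    ggplot2::theme_minimal()
}
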