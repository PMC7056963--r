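#' Plot the enrichment running sum for one gene set
#'
#' Diagnostic plot of the running-sum walk down the ranked list, with the
#' member positions marked as a rug and the enrichment score (the maximum
#' excursion before the terminal return to zero) highlighted.
#'
#' @inheritParams compute_es
#' @param main Plot title.
#' @return The running-sum vector, invisibly.
#' @export
plot_running_sum <- function(ranked, members, w = 1,
                             main = "Enrichment running sum") {
  rs <- running_sum(ranked, members, w)
  n <- length(rs)
  es <- max(rs[-n])
  plot(seq_len(n), rs, type = "l", xlab = "Rank in gene list",
       ylab = "Running enrichment statistic", main = main)
  graphics::abline(h = 0, lty = 3)
  hits <- which(ranked$genes %in% members)
  graphics::rug(hits, col = "red3")
  graphics::abline(h = es, col = "red3", lty = 2)
  graphics::mtext(sprintf("ES = %.4f", es), side = 3, adj = 1, cex = 0.8)
  invisible(rs)
}
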