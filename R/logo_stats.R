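# Two-sample, per-position nucleotide enrichment/depletion statistics
# between positive and negative fragment sets (the two-sample-logo
# computation).

#' Per-position nucleotide enrichment between two fragment sets
#'
#' For every (position, nucleotide) cell, each sequence contributes a
#' 0/1 indicator (does it carry that nucleotide at that position); the
#' two sets of indicators are compared with a two-sided two-sample
#' t-test (pooled-variance Student test by default, the two-sample-logo
#' convention; set `var_equal = FALSE` for the Welch variant). A cell
#' is called `enriched` when `p < alpha` and the positive-set frequency
#' exceeds the negative-set frequency, `depleted` in the opposite case,
#' `none` otherwise. No multiple-testing correction is applied (the
#' conventional, liberal per-cell threshold). Cells with zero variance
#' in both groups — notably the central U, present in every fragment of
#' both sets — get `p = NA` and call `none`.
#'
#' @param positives,negatives `fragment_dataset`s of equal fragment
#'   length (labels are ignored; membership defines the two groups).
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @return a data.frame of class `psi_logo` with one row per
#'   (position, nucleotide): `position` (1-based, for display),
#'   `position0` (0-based), `nt`, `freq_pos`, `freq_neg`,
#'   `t_statistic`, `p_value`, `call`.
#' @export
two_sample_logo <- function(positives, negatives, alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(positives, "fragment_dataset"),
            inherits(negatives, "fragment_dataset"))
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both fragment sets must be non-empty")
  }
  if (positives$window_length != negatives$window_length) {
    stop("fragment length mismatch: ", positives$window_length,
         " vs ", negatives$window_length)
  }
  w <- positives$window_length
  pm <- do.call(rbind, strsplit(positives$residues, ""))
  nm <- do.call(rbind, strsplit(negatives$residues, ""))
  grid <- expand.grid(nt = RNA_ALPHABET, position0 = 0:(w - 1L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    nt <- grid$nt[r]; j <- grid$position0[r] + 1L
    x <- as.numeric(pm[, j] == nt)
    y <- as.numeric(nm[, j] == nt)
    fx <- mean(x); fy <- mean(y)
    if (sd(x) == 0 && sd(y) == 0) {
      tt <- c(t = NA_real_, p = NA_real_)
    } else {
      ht <- t.test(x, y, var.equal = var_equal)
      tt <- c(t = unname(ht$statistic), p = ht$p.value)
    }
    call <- "none"
    if (!is.na(tt["p"]) && tt["p"] < alpha) {
      call <- if (fx > fy) "enriched" else if (fx < fy) "depleted" else "none"
    }
    data.frame(position = grid$position0[r] + 1L, position0 = grid$position0[r],
               nt = nt, freq_pos = fx, freq_neg = fy,
               t_statistic = tt[["t"]], p_value = tt[["p"]], call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "alpha") <- alpha
  class(out) <- c("psi_logo", "data.frame")
  out
}

#' Render a two-sample logo plot and its TSV table
#'
#' Writes the full cell table as TSV always, and a stacked-letter plot
#' in which significant letters have heights proportional to
#' `|freq_pos - freq_neg|`, enriched letters above the axis and
#' depleted letters below.
#'
#' @param stats a `psi_logo` from [two_sample_logo()].
#' @param out_prefix files `<prefix>.tsv` and `<prefix>.png` are
#'   written.
#' @return named character vector of the two paths, invisibly.
#' @export
render_logo <- function(stats, out_prefix) {
  tsv <- paste0(out_prefix, ".tsv")
  png <- paste0(out_prefix, ".png")
  write.table(stats[, c("position", "nt", "freq_pos", "freq_neg",
                        "t_statistic", "p_value", "call")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- stats[stats$call != "none", , drop = FALSE]
  if (nrow(sig) > 0) {
    sig$height <- abs(sig$freq_pos - sig$freq_neg) *
      ifelse(sig$call == "enriched", 1, -1)
    # stack letters outward from the axis within each position/side
    sig <- sig[order(sig$position, abs(sig$height)), ]
    sig$y <- stats::ave(sig$height, sig$position, sign(sig$height),
                        FUN = function(h) cumsum(h) - h / 2)
    p <- ggplot2::ggplot(sig, ggplot2::aes(x = .data$position, y = .data$y,
                                           label = .data$nt, color = .data$nt,
                                           size = abs(.data$height))) +
      ggplot2::geom_text(fontface = "bold", show.legend = FALSE) +
      ggplot2::scale_size_continuous(range = c(2, 8))
  } else {
    p <- ggplot2::ggplot(data.frame(position = stats$position, y = 0),
                         ggplot2::aes(x = .data$position, y = .data$y))
  }
  p <- p +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = unique(stats$position)) +
    ggplot2::labs(x = "fragment position (1-based)",
                  y = "frequency difference (positive - negative)",
                  title = "Two-sample logo: enriched (above) / depleted (below)") +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(png, p, width = 8, height = 3.5, dpi = 150)
  invisible(c(tsv = tsv, png = png))
}
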