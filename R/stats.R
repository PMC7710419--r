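#' Paired t-test on matched pre/post samples
#'
#' Classical paired t-test on the differences `post - pre`, two-sided
#' p-value from the t distribution with n - 1 degrees of freedom.
#'
#' @param pre,post Equal-length numeric vectors (>= 3 pairs) matched by
#'   pairing unit (epoch index or subject).
#' @return List with `t`, `p`, `df`, `direction` (sign of the mean
#'   difference post - pre).
#' @export
paired_ttest <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 3) stop("paired t-test needs at least 3 pairs")
  d <- post - pre
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1, direction = 0))
    stop("zero-variance differences: paired t-test undefined")
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), direction = sign(mean(d)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via `stats::p.adjust(method = "BH")`;
#' adjusted values are monotone in the raw p-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (non-empty).
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Channel-wise paired comparisons
#'
#' One paired t-test per channel (matrix column) between matched pre and
#' post observations, with optional FDR control.
#'
#' @param pre,post Matrices, pairing-unit x channels (e.g. per-epoch log10
#'   band power), equal dimensions.
#' @param alpha Significance level (default 0.05).
#' @param use_fdr Declare significance on BH-adjusted p-values (default
#'   TRUE) or raw p-values.
#' @return Data frame with `feature_id`, `t`, `p`, `p_adj`, `significant`,
#'   `direction` per channel.
#' @export
channel_tests <- function(pre, post, alpha = 0.05, use_fdr = TRUE) {
  if (!all(dim(pre) == dim(post))) stop("pre and post must have equal dimensions")
  res <- lapply(seq_len(ncol(pre)), function(ch) {
    tt <- paired_ttest(pre[, ch], post[, ch])
    data.frame(feature_id = colnames(pre)[ch] %||% as.character(ch),
               t = tt$t, p = tt$p, direction = tt$direction)
  })
  out <- do.call(rbind, res)
  out$p_adj <- fdr_adjust(out$p)
  out$significant <- if (use_fdr) out$p_adj < alpha else out$p < alpha
  out[, c("feature_id", "t", "p", "p_adj", "significant", "direction")]
}

#' Edge-wise paired coherence comparisons
#'
#' Computes per-epoch band coherence matrices for both states, truncates
#' both to the smaller epoch count, and runs one paired t-test per channel
#' pair (C(n, 2) edges, 120 for 16 channels) with the post - pre direction
#' recorded for enhanced/weakened classification.
#'
#' @param pre_epochs,post_epochs [new_epoch_set()]s with >= 2 retained
#'   epochs each.
#' @param band A [band_definition()].
#' @param alpha Significance level (default 0.05, on raw p-values, with
#'   FDR-adjusted values co-reported).
#' @param use_fdr Declare significance on adjusted p-values instead
#'   (default FALSE).
#' @param window_s,overlap Welch parameters.
#' @return Data frame with `ch_i`, `ch_j`, `t`, `p`, `p_adj`,
#'   `significant`, `direction` per edge.
#' @export
edge_tests <- function(pre_epochs, post_epochs, band, alpha = 0.05,
                       use_fdr = FALSE, window_s = 2, overlap = 0.5) {
  pre_c <- coherence_by_epoch(pre_epochs, band, window_s, overlap)
  post_c <- coherence_by_epoch(post_epochs, band, window_s, overlap)
  nep <- min(dim(pre_c)[1], dim(post_c)[1])
  if (nep < 3) stop("edge tests need at least 3 paired epochs")
  labels <- pre_epochs$channel_labels
  nch <- length(labels)
  rows <- list()
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      tt <- paired_ttest(pre_c[seq_len(nep), i, j], post_c[seq_len(nep), i, j])
      rows[[length(rows) + 1L]] <- data.frame(
        ch_i = labels[i], ch_j = labels[j], t = tt$t, p = tt$p,
        direction = tt$direction)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_adjust(out$p)
  out$significant <- if (use_fdr) out$p_adj < alpha else out$p < alpha
  out[, c("ch_i", "ch_j", "t", "p", "p_adj", "significant", "direction")]
}

#' Correlation of a network metric with seizure order
#'
#' Pearson correlation between an ordered series of network metric values
#' (segments 1-pre, 1-post, ..., k-post) and segment rank, with a
#' two-sided p-value. A positive trend in characteristic path length (or a
#' negative one in clustering coefficient) indicates progressive network
#' degradation across consecutive seizures.
#'
#' @param values Numeric metric series in temporal segment order (>= 3).
#' @param metric,band Optional labels carried into the result.
#' @return List of class `trend_result` with `metric`, `band`, `r`, `p`,
#'   `n_points`.
#' @export
seizure_trend <- function(values, metric = NA_character_, band = NA_character_) {
  if (length(values) < 3) stop("trend needs at least 3 segments")
  if (stats::sd(values) == 0) stop("constant metric series: correlation undefined")
  ct <- stats::cor.test(values, seq_along(values), method = "pearson")
  structure(list(metric = metric, band = band, r = unname(ct$estimate),
                 p = ct$p.value, n_points = length(values)),
            class = "trend_result")
}
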