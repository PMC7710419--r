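#' Extract pre/post windows around an annotated seizure
#'
#' Pre window is `[onset - window, onset)`, post window is
#' `(offset, offset + window]` (times in seconds from recording start).
#'
#' @param recording A [new_recording()].
#' @param onset,offset Seizure onset/offset in seconds.
#' @param window Window length in seconds (default 600 = 10 min).
#' @param guard_s Gap between the seizure boundary and the window
#'   (default 0).
#' @param seizure_index Label carried into the extracted recordings.
#' @return List with `pre` and `post` recordings, ids
#'   `"<seizure_index>-pre"` / `"-post"`.
#' @export
extract_peri_seizure <- function(recording, onset, offset, window = 600,
                                 guard_s = 0, seizure_index = 1L) {
  fs <- recording$fs
  dur <- recording_duration(recording)
  pre_start <- onset - guard_s - window
  post_end <- offset + guard_s + window
  if (pre_start < 0 || post_end > dur) {
    stop(sprintf(
      "seizure %d: need %g s on both sides but only %.1f s before onset and %.1f s after offset are available",
      seizure_index, window + guard_s, onset, dur - offset))
  }
  slice <- function(t0, t1, state) {
    idx <- (round(t0 * fs) + 1L):round(t1 * fs)
    new_recording(recording$data[, idx, drop = FALSE], fs,
                  channel_labels = recording$channel_labels,
                  id = sprintf("%d-%s", seizure_index, state))
  }
  list(pre = slice(pre_start, onset - guard_s, "pre"),
       post = slice(offset + guard_s, post_end, "post"))
}

#' Assemble a run configuration
#'
#' Bundles every tunable of the end-to-end pipeline with validated
#' defaults. `input` is either a [synth_config()] (synthetic study) or a
#' data frame of EDF paths with `onset_s` / `offset_s` annotations.
#'
#' @param input A [synth_config()], or a data frame with columns `path`
#'   (EDF file whose sidecar/annotations hold seizure marks).
#' @param n_seizures Number of seizure pre/post pairs (synthetic input).
#' @param bands Band definitions.
#' @param band_low_hz,band_high_hz,epoch_s,reject_uv,reject_inclusive
#'   Preprocessing parameters.
#' @param window_s,overlap Welch parameters.
#' @param entropy A [fuzzyen_params()].
#' @param entropy_band Band name to filter to before entropy (default
#'   `"delta"`; `NA` for broadband).
#' @param alpha_psd,alpha_entropy,alpha_edges Significance levels for the
#'   channel PSD tests (raw p), entropy tests (FDR-adjusted) and edge
#'   tests (raw p).
#' @param edge_band Band for the edge-wise tests (default `"delta"`).
#' @param seed Integer seed (synthetic input).
#' @return List of class `run_config`.
#' @export
run_config <- function(input, n_seizures = 1L, bands = default_bands(),
                       band_low_hz = 1, band_high_hz = 45, epoch_s = 6,
                       reject_uv = 80, reject_inclusive = FALSE,
                       window_s = 2, overlap = 0.5,
                       entropy = fuzzyen_params(), entropy_band = "delta",
                       alpha_psd = 0.05, alpha_entropy = 0.01,
                       alpha_edges = 0.05, edge_band = "delta", seed = 1L) {
  if (!(inherits(input, "synth_config") || is.data.frame(input))) {
    stop("input must be a synth_config or a data frame of EDF paths")
  }
  check_bands(bands)
  structure(as.list(environment()), class = "run_config")
}

gather_recordings <- function(config) {
  if (inherits(config$input, "synth_config")) {
    if (config$n_seizures >= 2) {
      generate_seizure_series(config$input, config$n_seizures)
    } else {
      recs <- list(generate_recording(config$input, "pre", 1L),
                   generate_recording(config$input, "post", 1L))
      stats::setNames(recs, vapply(recs, `[[`, character(1), "id"))
    }
  } else {
    out <- list()
    s <- 0L
    for (p in config$input$path) {
      rec <- read_edf(p)
      ann <- rec$annotations
      if (!nrow(ann)) stop("no seizure annotations found for ", p)
      for (k in seq_len(nrow(ann))) {
        s <- s + 1L
        pair <- extract_peri_seizure(rec, ann$onset_s[k], ann$offset_s[k],
                                     seizure_index = s)
        out[[pair$pre$id]] <- pair$pre
        out[[pair$post$id]] <- pair$post
      }
    }
    out
  }
}

#' Run the full peri-ictal analysis pipeline
#'
#' Executes, in fixed order: input assembly (synthetic generation or EDF
#' extraction), preprocessing (average re-reference, band-pass, epoching,
#' artifact rejection), Welch band power, band-limited fuzzy entropy,
#' pooled coherence networks and graph metrics per band, channel-/edge-
#' wise paired statistics between each pre/post pair, and (with >= 3
#' segments) the metric-versus-segment-order trend. All tables are written
#' as CSV plus a JSON summary and run manifest when `out_dir` is given;
#' outputs are a pure function of the configuration (identical config and
#' seed give byte-identical files).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @param entropy_channels Optional subset of channels for the entropy
#'   stage (labels or indices); default all.
#' @return List of class `run_report` with elements `features` (per
#'   epoch/channel/band tables), `band_power_tests`, `entropy_tests`,
#'   `edge_tests`, `metrics`, `trends`, `retention`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, entropy_channels = NULL) {
  stopifnot(inherits(config, "run_config"))
  recs <- gather_recordings(config)
  labels <- names(recs)

  epoch_sets <- list()
  retention <- list()
  for (lb in labels) {
    prov <- strsplit(lb, "-", fixed = TRUE)[[1]]
    ep <- preprocess(recs[[lb]], config$band_low_hz, config$band_high_hz,
                     config$epoch_s, config$reject_uv, config$reject_inclusive,
                     provenance = list(id = lb, seizure_index = as.integer(prov[1]),
                                       state = prov[2]))
    epoch_sets[[lb]] <- ep
    retention[[lb]] <- data.frame(segment = lb,
                                  epochs_total = length(ep$retained_mask),
                                  epochs_retained = sum(ep$retained_mask))
  }
  retention <- do.call(rbind, retention)
  rownames(retention) <- NULL

  bands <- config$bands
  band_names <- vapply(bands, `[[`, character(1), "name")
  eband <- if (!is.na(config$entropy_band)) bands[[config$entropy_band]]

  features <- list()
  metrics <- list()
  power_arrays <- list()
  entropy_mats <- list()
  for (lb in labels) {
    ep <- epoch_sets[[lb]]
    pw <- epoch_band_power(ep, bands, config$window_s, config$overlap,
                           log10 = FALSE)
    power_arrays[[lb]] <- log10(pw)
    en <- epoch_entropy(ep, config$entropy, band = eband,
                        channels = entropy_channels)
    entropy_mats[[lb]] <- en$per_epoch
    prov <- strsplit(lb, "-", fixed = TRUE)[[1]]
    mean_pw <- apply(pw, c(2, 3), mean)
    features[[lb]] <- data.frame(
      segment = lb, seizure_index = as.integer(prov[1]), state = prov[2],
      channel = rep(rownames(mean_pw), times = ncol(mean_pw)),
      band = rep(colnames(mean_pw), each = nrow(mean_pw)),
      power_uv2 = as.vector(mean_pw),
      log10_power = as.vector(log10(mean_pw)),
      fuzzy_entropy = as.vector(en$values[match(rownames(mean_pw), names(en$values))]))
    bm <- band_metrics(ep, bands, config$window_s, config$overlap)
    bm <- cbind(segment = lb, seizure_index = as.integer(prov[1]),
                state = prov[2], bm)
    metrics[[lb]] <- bm
  }
  features <- do.call(rbind, features); rownames(features) <- NULL
  metrics <- do.call(rbind, metrics); rownames(metrics) <- NULL

  n_seiz <- max(metrics$seizure_index)
  bp_tests <- list()
  en_tests <- list()
  eg_tests <- list()
  for (s in seq_len(n_seiz)) {
    pre_lb <- sprintf("%d-pre", s); post_lb <- sprintf("%d-post", s)
    nep <- min(dim(power_arrays[[pre_lb]])[1], dim(power_arrays[[post_lb]])[1])
    for (bn in band_names) {
      tt <- channel_tests(power_arrays[[pre_lb]][seq_len(nep), , bn],
                          power_arrays[[post_lb]][seq_len(nep), , bn],
                          alpha = config$alpha_psd, use_fdr = FALSE)
      bp_tests[[paste(s, bn)]] <- cbind(seizure_index = s, band = bn, tt)
    }
    et <- channel_tests(entropy_mats[[pre_lb]][seq_len(nep), , drop = FALSE],
                        entropy_mats[[post_lb]][seq_len(nep), , drop = FALSE],
                        alpha = config$alpha_entropy, use_fdr = TRUE)
    en_tests[[as.character(s)]] <- cbind(seizure_index = s,
                                         band = if (is.null(eband)) "broadband" else eband$name,
                                         et)
    eg <- edge_tests(epoch_sets[[pre_lb]], epoch_sets[[post_lb]],
                     bands[[config$edge_band]], alpha = config$alpha_edges,
                     use_fdr = FALSE, window_s = config$window_s,
                     overlap = config$overlap)
    eg_tests[[as.character(s)]] <- cbind(seizure_index = s,
                                         band = config$edge_band, eg)
  }
  bp_tests <- do.call(rbind, bp_tests); rownames(bp_tests) <- NULL
  en_tests <- do.call(rbind, en_tests); rownames(en_tests) <- NULL
  eg_tests <- do.call(rbind, eg_tests); rownames(eg_tests) <- NULL

  trends <- NULL
  if (nrow(metrics) / length(bands) >= 3) {
    ord <- order(metrics$seizure_index, metrics$state != "pre")
    m <- metrics[ord, ]
    rows <- list()
    for (bn in band_names) {
      mb <- m[m$band == bn, ]
      for (var in c("cpl", "cc_printed", "cc_standard")) {
        # a degenerate (constant) series, e.g. printed-variant CC on very
        # sparse networks, yields NA rather than aborting the run
        tr <- tryCatch(seizure_trend(mb[[var]], metric = var, band = bn),
                       error = function(e) list(r = NA_real_, p = NA_real_,
                                                n_points = nrow(mb)))
        rows[[paste(bn, var)]] <- data.frame(band = bn, metric = var,
                                             r = tr$r, p = tr$p,
                                             n_points = tr$n_points)
      }
    }
    trends <- do.call(rbind, rows); rownames(trends) <- NULL
  }

  manifest <- list(
    seed = if (inherits(config$input, "synth_config")) config$input$seed else config$seed,
    n_segments = length(labels), segments = labels,
    epoch_s = config$epoch_s, reject_uv = config$reject_uv,
    band_low_hz = config$band_low_hz, band_high_hz = config$band_high_hz,
    welch_window_s = config$window_s, welch_overlap = config$overlap,
    entropy = unclass(config$entropy),
    alphas = list(psd = config$alpha_psd, entropy = config$alpha_entropy,
                  edges = config$alpha_edges),
    retention = retention)

  report <- structure(
    list(features = features, band_power_tests = bp_tests,
         entropy_tests = en_tests, edge_tests = eg_tests, metrics = metrics,
         trends = trends, retention = retention, manifest = manifest),
    class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a run report's tables to disk
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wr(report$features, "features.csv")
  wr(report$band_power_tests, "band_power_tests.csv")
  wr(report$entropy_tests, "entropy_tests.csv")
  wr(report$edge_tests, "edge_tests.csv")
  wr(report$metrics, "network_metrics.csv")
  wr(report$trends, "trends.csv")
  wr(report$retention, "retention.csv")
  summary <- list(
    significant_psd_channels = with(report$band_power_tests,
      split(feature_id[significant], paste(seizure_index[significant], band[significant]))),
    enhanced_edges = with(report$edge_tests,
      paste(ch_i, ch_j, sep = "-")[significant & direction > 0]),
    weakened_edges = with(report$edge_tests,
      paste(ch_i, ch_j, sep = "-")[significant & direction < 0]),
    trends = report$trends)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report>: %d segments, %d/%d epochs retained\n",
              x$manifest$n_segments, sum(x$retention$epochs_retained),
              sum(x$retention$epochs_total)))
  cat(sprintf("  significant PSD channel tests: %d of %d\n",
              sum(x$band_power_tests$significant), nrow(x$band_power_tests)))
  cat(sprintf("  significant edges: %d of %d\n",
              sum(x$edge_tests$significant), nrow(x$edge_tests)))
  if (!is.null(x$trends)) {
    d <- x$trends[x$trends$band == "delta" & x$trends$metric %in% c("cpl", "cc_printed"), ]
    for (i in seq_len(nrow(d))) {
      cat(sprintf("  delta %s trend: r = %.3f, p = %.3f\n",
                  d$metric[i], d$r[i], d$p[i]))
    }
  }
  invisible(x)
}
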