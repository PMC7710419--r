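as_conn_matrix <- function(C) {
  if (inherits(C, "connectivity_matrix")) C <- C$C
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("connectivity matrix must be square")
  if (max(abs(C - t(C))) > 1e-9) stop("connectivity matrix must be symmetric")
  if (any(C < 0)) stop("connectivity weights must be nonnegative")
  diag(C) <- 0
  C
}

#' Characteristic path length of a weighted similarity network
#'
#' Edges carry length `1 / C_ij` for `C_ij > 0` (no edge at zero weight;
#' set `weight_to_length = "one_minus"` for `1 - C_ij`). `d_ij` is the
#' all-pairs shortest weighted path over those lengths, and the
#' characteristic path length is the mean of `d_ij` over ordered pairs
#' `i != j`. Lower values indicate stronger global integration.
#'
#' @param C A `connectivity_matrix` or symmetric nonnegative matrix with
#'   zero diagonal.
#' @param weight_to_length `"inverse"` (default) or `"one_minus"`.
#' @param disconnected `"error"` (default) or `"efficiency"`: for a
#'   disconnected graph either fail, or return the harmonic-mean form
#'   `1 / E` with `E` the mean of `1 / d_ij` (reported as such via the
#'   `"efficiency"` attribute).
#' @return Characteristic path length (dimensionless).
#' @export
characteristic_path_length <- function(C, weight_to_length = c("inverse", "one_minus"),
                                       disconnected = c("error", "efficiency")) {
  weight_to_length <- match.arg(weight_to_length)
  disconnected <- match.arg(disconnected)
  C <- as_conn_matrix(C)
  n <- nrow(C)
  len <- matrix(0, n, n)
  pos <- C > 0
  len[pos] <- switch(weight_to_length,
                     inverse = 1 / C[pos],
                     one_minus = 1 - C[pos])
  g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  off <- d[row(d) != col(d)]
  if (any(!is.finite(off))) {
    if (disconnected == "error") {
      stop("graph is disconnected: characteristic path length undefined (use disconnected = \"efficiency\")")
    }
    eff <- mean(1 / off)
    return(structure(1 / eff, efficiency = eff))
  }
  mean(off)
}

#' Weighted clustering coefficient
#'
#' Per node, the triangle intensity `sum_{j,h} (C_ij C_ih C_jh)^(1/3)` is
#' normalized and averaged over nodes. Two normalizations are provided:
#'
#' * `variant = "printed"`: denominator `s_i (s_i - 1)` with node strength
#'   `s_i = sum_j C_ij` — the headline variant. A node with strength <= 1
#'   contributes 0 (with a warning), since its denominator is not positive.
#'   Note this form is not invariant to uniform weight scaling.
#' * `variant = "standard"`: the conventional weighted form with
#'   denominator `k_i (k_i - 1)`, `k_i` the count of nonzero edges at node
#'   i; nodes with fewer than two edges contribute 0.
#'
#' Both equal 1 on a complete graph with unit weights.
#'
#' @param C A `connectivity_matrix` or symmetric nonnegative matrix.
#' @param variant `"printed"` (default) or `"standard"`.
#' @return Clustering coefficient (mean over nodes).
#' @export
clustering_coefficient <- function(C, variant = c("printed", "standard")) {
  variant <- match.arg(variant)
  C <- as_conn_matrix(C)
  n <- nrow(C)
  W <- C^(1 / 3)
  num <- diag(W %*% W %*% W)      # sum_{j,h} (C_ij C_ih C_jh)^(1/3)
  if (variant == "printed") {
    s <- rowSums(C)
    den <- s * (s - 1)
    bad <- den <= 0 & num > 0
    if (any(bad)) {
      warning(sprintf("%d node(s) with strength <= 1: their clustering terms are set to 0",
                      sum(bad)))
    }
    terms <- ifelse(den > 0, num / den, 0)
  } else {
    k <- rowSums(C > 0)
    den <- k * (k - 1)
    terms <- ifelse(den > 0, num / den, 0)
  }
  mean(terms)
}

#' Proportional threshold of a connectivity matrix
#'
#' Keeps the strongest `density` fraction of edges (by weight) and zeroes
#' the rest. Intended for sensitivity analyses only: the pipeline's
#' headline metrics use the full weighted matrix, since no density
#' threshold is standard for coherence networks.
#'
#' @param C A `connectivity_matrix` or symmetric nonnegative matrix.
#' @param density Fraction of edges to keep, in (0, 1].
#' @return The thresholded matrix (plain matrix, symmetric, zero diagonal).
#' @export
proportional_threshold <- function(C, density) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  C <- as_conn_matrix(C)
  w <- C[upper.tri(C)]
  keep <- ceiling(density * sum(w > 0))
  if (keep < sum(w > 0)) {
    cut <- sort(w[w > 0], decreasing = TRUE)[keep]
    C[C < cut] <- 0
  }
  C
}

#' Graph metrics of one connectivity matrix
#'
#' @param C A `connectivity_matrix` or plain matrix.
#' @param ... Passed to [characteristic_path_length()].
#' @return List with `cpl`, `cc_printed`, `cc_standard`.
#' @export
network_metrics <- function(C, ...) {
  list(cpl = characteristic_path_length(C, ...),
       cc_printed = clustering_coefficient(C, "printed"),
       cc_standard = clustering_coefficient(C, "standard"))
}

#' Band-wise network metrics of an epoch set
#'
#' Builds the pooled coherence matrix per band and evaluates the graph
#' metrics on each.
#'
#' @param epochs A [new_epoch_set()] (or a named list of connectivity
#'   matrices keyed by band name).
#' @param bands Band definitions.
#' @param window_s,overlap Welch parameters for the coherence matrices.
#' @param ... Passed to [characteristic_path_length()].
#' @return Data frame with one row per band: `band`, `cpl`, `cc_printed`,
#'   `cc_standard`.
#' @export
band_metrics <- function(epochs, bands = default_bands(), window_s = 2,
                         overlap = 0.5, ...) {
  rows <- lapply(bands, function(b) {
    C <- if (inherits(epochs, "epoch_set")) {
      coherence_matrix(epochs, b, window_s, overlap)
    } else {
      epochs[[b$name]]
    }
    m <- network_metrics(C, ...)
    data.frame(band = b$name, cpl = m$cpl, cc_printed = m$cc_printed,
               cc_standard = m$cc_standard)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
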