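# Feature-set constructors for the network-interaction and edge-metric sets.
# A FeatureSet is a plain numeric matrix (subjects x elements) with unique
# column labels and a "set_name" attribute; constructors fix the element
# order so indices are comparable across runs.

#' Construct a FeatureSet
#'
#' @param x numeric matrix, subjects x elements, with column names.
#' @param name feature-set name.
#' @return The matrix with class `feature_set` and attribute `set_name`.
#' @export
feature_set <- function(x, name) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("feature set requires unique element labels")
  if (anyNA(x)) stop("feature set must not contain missing values")
  structure(x, set_name = name, class = c("feature_set", class(x)))
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s': %d subjects x %d elements>\n",
              attr(x, "set_name"), nrow(x), ncol(x)))
  invisible(x)
}

#' Enumerate network/region pairs in canonical row-major order
#'
#' @param n number of nodes.
#' @param labels optional node labels (default `N01..`).
#' @param directed if `TRUE`, all ordered pairs i != j; otherwise unordered
#'   pairs i < j.
#' @return Data frame with columns `i`, `j`, `label`.
#' @export
node_pairs <- function(n, labels = sprintf("N%02d", seq_len(n)),
                       directed = FALSE) {
  stopifnot(n >= 2L, length(labels) == n)
  if (directed) {
    idx <- expand.grid(j = seq_len(n), i = seq_len(n))[, c("i", "j")]
    idx <- idx[idx$i != idx$j, ]
  } else {
    idx <- expand.grid(j = seq_len(n), i = seq_len(n))[, c("i", "j")]
    idx <- idx[idx$i < idx$j, ]
  }
  idx <- idx[order(idx$i, idx$j), ]
  rownames(idx) <- NULL
  sep <- if (directed) "->" else "~"
  idx$label <- paste(labels[idx$i], labels[idx$j], sep = sep)
  idx
}

#' Static functional connectivity of network time series
#'
#' One Fisher z-transformed Pearson correlation per unordered network pair,
#' in row-major upper-triangle order over the canonical network ordering.
#' 15 networks yield 105 elements.
#'
#' @param series numeric matrix, networks x time points (rows = networks).
#' @param labels optional network labels.
#' @param cap correlations are clipped to `[-cap, cap]` before `atanh`.
#' @return Named numeric vector over unordered pairs.
#' @export
static_fc <- function(series, labels = NULL, cap = 1 - 1e-6) {
  series <- as.matrix(series)
  if (ncol(series) < 3L) stop("need at least 3 time points")
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) stop("degenerate series: constant channel")
  n <- nrow(series)
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(n))
  pr <- node_pairs(n, labels)
  R <- stats::cor(t(series))
  r <- R[cbind(pr$i, pr$j)]
  z <- atanh(pmin(pmax(r, -cap), cap))
  stats::setNames(z, pr$label)
}

#' Vectorize a symmetric edge-metric matrix
#'
#' Row-major upper-triangle vectorization of a symmetric region x region
#' matrix (diagonal ignored); 84 regions yield 3486 elements.
#'
#' @param m symmetric numeric matrix.
#' @param tol asymmetry tolerance.
#' @return Named numeric vector over unordered region pairs.
#' @export
vectorize_edge_matrix <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol)
    stop("edge-metric matrix must be symmetric")
  labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(m)))
  pr <- node_pairs(nrow(m), labels)
  stats::setNames(m[cbind(pr$i, pr$j)], pr$label)
}

#' Rebuild a symmetric matrix from its edge vector
#'
#' Inverse of [vectorize_edge_matrix()]; the diagonal is set to `diag`.
#'
#' @param v edge vector in row-major upper-triangle order.
#' @param n number of regions.
#' @param diag value for the diagonal.
#' @return Symmetric `n` x `n` matrix.
#' @export
unvectorize_edge_matrix <- function(v, n, diag = 0) {
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(diag, n, n)
  pr <- node_pairs(n)
  m[cbind(pr$i, pr$j)] <- v
  m[cbind(pr$j, pr$i)] <- v
  m
}

#' Network-interaction feature sets from per-subject time series
#'
#' Computes the three resting-state feature sets from a list of per-subject
#' network x time matrices: static FC (`sFC`, 105 elements for 15 networks),
#' number of coherence clusters (`nCC`, 105), and lead coherence
#' (`leadCoh`, 210 directed elements). For each unordered pair one wavelet
#' coherence map is computed; `leadCoh(i->j)` is the leading fraction and
#' `leadCoh(j->i)` its complement restricted to significant lagging cells.
#'
#' @param series_list list of numeric matrices (networks x time), one per
#'   subject, identical dimensions.
#' @param dt sampling interval in seconds.
#' @param labels optional network labels.
#' @param lead_mode passed to [lead_coherence()].
#' @param ... further arguments to [wavelet_coherence()].
#' @return Named list of `feature_set` objects: `sFC`, `nCC`, `leadCoh`.
#' @export
network_feature_sets <- function(series_list, dt, labels = NULL,
                                 lead_mode = "binary", ...) {
  stopifnot(length(series_list) >= 1L)
  n_net <- nrow(series_list[[1L]])
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(n_net))
  pu <- node_pairs(n_net, labels, directed = FALSE)
  pd <- node_pairs(n_net, labels, directed = TRUE)
  ns <- length(series_list)
  sfc <- matrix(NA_real_, ns, nrow(pu), dimnames = list(NULL, pu$label))
  ncc <- matrix(NA_real_, ns, nrow(pu), dimnames = list(NULL, pu$label))
  lead <- matrix(NA_real_, ns, nrow(pd), dimnames = list(NULL, pd$label))
  key <- function(i, j) paste0(i, "_", j)
  for (s in seq_len(ns)) {
    ts <- as.matrix(series_list[[s]])
    sfc[s, ] <- static_fc(ts, labels)
    vals <- new.env(parent = emptyenv())
    for (p in seq_len(nrow(pu))) {
      i <- pu$i[p]; j <- pu$j[p]
      map <- wavelet_coherence(ts[i, ], ts[j, ], dt,
                               pair = labels[c(i, j)], ...)
      ncc[s, p] <- count_coherence_clusters(map)
      assign(key(i, j), lead_coherence(map, lead_mode), envir = vals)
      # swapped pair: phase negates, magnitude and mask unchanged
      rev_map <- map
      rev_map$phase <- -map$phase
      rev_map$pair <- rev(map$pair)
      assign(key(j, i), lead_coherence(rev_map, lead_mode), envir = vals)
    }
    for (p in seq_len(nrow(pd)))
      lead[s, p] <- get(key(pd$i[p], pd$j[p]), envir = vals)
  }
  rn <- names(series_list)
  rownames(sfc) <- rownames(ncc) <- rownames(lead) <- rn
  list(sFC = feature_set(sfc, "sFC"),
       nCC = feature_set(ncc, "nCC"),
       leadCoh = feature_set(lead, "leadCoh"))
}
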