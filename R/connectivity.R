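#' Row-major lower-triangle edge index
#'
#' Enumerates the R(R-1)/2 undirected edges of an R-region matrix in
#' row-major lower-triangle order: (2,1), (3,1), (3,2), (4,1), ...
#'
#' @param R number of regions.
#' @return data.frame with integer columns \code{i}, \code{j} (i > j).
#' @export
lower_edge_index <- function(R) {
  if (R < 2L) stop("need at least 2 regions")
  i <- rep.int(2:R, 1:(R - 1L))
  j <- unlist(lapply(2:R, function(k) seq_len(k - 1L)), use.names = FALSE)
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' First-level ROI-to-ROI connectivity
#'
#' Pearson-correlates every pair of region time series and applies the
#' Fisher z-transform. Correlations are clipped to [-1 + 1e-7, 1 - 1e-7]
#' before atanh so degenerate (duplicated) columns cannot produce
#' infinite z. The diagonal is stored as 0 and treated as masked.
#'
#' @param ts numeric T x R matrix of time series (T >= 3 rows).
#' @param region_labels region names; default column names of \code{ts}.
#' @return Object of class \code{conn_matrix}: list with
#'   \code{region_labels} and symmetric \code{z}.
#' @examples
#' ts <- cbind(a = c(1, 2, 3), b = c(1, 3, 2), c = c(2, 1, 3))
#' compute_connectivity(ts)$z
#' @export
compute_connectivity <- function(ts, region_labels = colnames(ts)) {
  if (!is.matrix(ts)) ts <- as.matrix(ts)
  if (nrow(ts) < 3L) stop("need at least 3 timepoints (T >= 3)")
  if (is.null(region_labels)) {
    region_labels <- paste0("region_", seq_len(ncol(ts)))
  }
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series in region(s): ",
         paste(region_labels[sds == 0], collapse = ", "))
  }
  eps <- 1e-7
  r <- stats::cor(ts)
  r <- pmin(pmax(r, -1 + eps), 1 - eps)
  z <- atanh(r)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  dimnames(z) <- list(region_labels, region_labels)
  structure(list(region_labels = region_labels, z = z),
            class = "conn_matrix")
}

conn_values <- function(m) {
  if (inherits(m, "conn_matrix")) return(m$z)
  if (inherits(m, "effect_matrix")) return(m$effect)
  if (is.matrix(m)) return(m)
  stop("expected a conn_matrix, effect_matrix, or plain matrix")
}

#' Vectorize the lower triangle of a symmetric matrix
#'
#' Returns edge values in row-major lower-triangle order (see
#' [lower_edge_index()]); the order is stable for a fixed label order, so
#' vectors from different matrices over the same regions are aligned.
#'
#' @param m \code{conn_matrix}, \code{effect_matrix}, or symmetric matrix.
#' @param tol asymmetry tolerance.
#' @return Numeric vector of length R(R-1)/2, named "row ~ col".
#' @export
vectorize_lower <- function(m, tol = 1e-9) {
  v <- conn_values(m)
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > tol) {
    stop("matrix is not symmetric within tolerance ", tol)
  }
  idx <- lower_edge_index(nrow(v))
  out <- v[cbind(idx$i, idx$j)]
  labs <- rownames(v)
  if (!is.null(labs)) {
    names(out) <- paste(labs[idx$i], labs[idx$j], sep = " ~ ")
  }
  out
}

#' Stack connectivity matrices into a subjects-by-edges matrix
#'
#' @param conn_list named list of \code{conn_matrix} objects sharing the
#'   same region labels (names become row names, typically subject ids).
#' @return n x R(R-1)/2 matrix with attributes \code{region_labels} and
#'   \code{edge_index}.
#' @export
stack_connectivity <- function(conn_list) {
  if (length(conn_list) == 0L) stop("empty connectivity list")
  labels <- conn_list[[1L]]$region_labels
  for (m in conn_list) {
    if (!identical(m$region_labels, labels)) {
      stop("all connectivity matrices must share region labels and order")
    }
  }
  Y <- t(vapply(conn_list, vectorize_lower,
                numeric(length(labels) * (length(labels) - 1L) / 2L)))
  rownames(Y) <- names(conn_list)
  attr(Y, "region_labels") <- labels
  attr(Y, "edge_index") <- lower_edge_index(length(labels))
  Y
}

# Rebuild a symmetric matrix from a lower-triangle edge vector.
fill_symmetric <- function(v, labels, diag_value = 0) {
  R <- length(labels)
  idx <- lower_edge_index(R)
  m <- matrix(diag_value, R, R, dimnames = list(labels, labels))
  m[cbind(idx$i, idx$j)] <- v
  m[cbind(idx$j, idx$i)] <- v
  m
}
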