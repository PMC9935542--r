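#' @name network_fnc
#' @title Functional network connectivity (set-level) analyses
#' @description Set-level tests of the overall connectivity within or
#'   between groups of regions, data-driven network definition by
#'   hierarchical clustering of connectivity profiles, and ROI-level seed
#'   analyses with FDR over targets.
NULL

# column of the stacked edge vector holding edge (i, j), i > j
edge_column <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (hi - 1L) * (hi - 2L) / 2L + lo
}

set_edge_columns <- function(labels, set_a, set_b = NULL) {
  a <- match(set_a, labels)
  if (any(is.na(a))) {
    stop("unknown region(s): ", paste(set_a[is.na(a)], collapse = ", "))
  }
  if (is.null(set_b)) {
    if (length(a) < 2L) stop("within-network set needs >= 2 regions")
    pr <- utils::combn(a, 2L)
    return(edge_column(pr[1L, ], pr[2L, ]))
  }
  b <- match(set_b, labels)
  if (any(is.na(b))) {
    stop("unknown region(s): ", paste(set_b[is.na(b)], collapse = ", "))
  }
  if (length(intersect(a, b)) > 0L) {
    stop("between-network sets must be disjoint")
  }
  g <- expand.grid(a = a, b = b)
  edge_column(g$a, g$b)
}

network_regions <- function(x) {
  if (inherits(x, "network_def")) x$regions else x
}

network_name <- function(x, default) {
  if (inherits(x, "network_def")) x$name else default
}

align_stack_design <- function(conn_stack, design) {
  focus <- attr(design, "focus")
  if (!is.null(rownames(conn_stack)) && !is.null(rownames(design))) {
    keep <- intersect(rownames(design), rownames(conn_stack))
    design <- design[rownames(design) %in% keep, , drop = FALSE]
    conn_stack <- conn_stack[rownames(design), , drop = FALSE]
  }
  if (nrow(conn_stack) != nrow(design)) {
    stop("conn_stack and design have different numbers of subjects")
  }
  attr(design, "focus") <- focus
  list(Y = conn_stack, X = design)
}

#' Set-level (functional network) connectivity test
#'
#' The per-subject mean Fisher-z over all edges between \code{set_a} and
#' \code{set_b} (or within \code{set_a} when \code{set_b} is NULL) is the
#' set-level response; the design's contrast is then a single GLM on that
#' scalar. Per-edge post-hoc GLMs populate the contributing-edge list
#' (uncorrected p < \code{p_unc}).
#'
#' @param conn_stack subjects x edges matrix ([stack_connectivity()]).
#' @param design design matrix with a \code{focus} attribute; an
#'   intercept-only design (focus "intercept") turns the test into a
#'   one-sample t-test on a stack of paired contrast values.
#' @param set_a,set_b [network_def()] objects or region-name vectors.
#' @param alternative sidedness.
#' @param p_unc uncorrected threshold for contributing edges.
#' @return Object of class \code{fnc_result}: \code{networks},
#'   \code{type}, \code{effect}, \code{statistic}, \code{df}, \code{p},
#'   \code{contributing_edges} (data.frame).
#' @export
fnc_test <- function(conn_stack, design, set_a, set_b = NULL,
                     alternative = "two.sided", p_unc = 0.05) {
  labels <- attr(conn_stack, "region_labels")
  if (is.null(labels)) stop("conn_stack lacks region_labels attribute")
  cols <- set_edge_columns(labels, network_regions(set_a),
                           if (is.null(set_b)) NULL
                           else network_regions(set_b))
  if (length(cols) == 0L) stop("empty edge set")
  ad <- align_stack_design(conn_stack, design)
  scalar <- rowMeans(ad$Y[, cols, drop = FALSE])
  focus <- attr(design, "focus")
  fit <- ols_t(ad$X, cbind(scalar), focus, alternative)
  edge_fit <- ols_t(ad$X, ad$Y[, cols, drop = FALSE], focus, alternative)
  idx <- lower_edge_index(length(labels))
  contrib <- data.frame(
    region_a = labels[idx$i[cols]],
    region_b = labels[idx$j[cols]],
    effect = unname(edge_fit$beta),
    t = unname(edge_fit$t),
    p_unc = unname(edge_fit$p),
    stringsAsFactors = FALSE)
  contrib <- contrib[contrib$p_unc < p_unc, , drop = FALSE]
  rownames(contrib) <- NULL
  structure(list(
    networks = c(network_name(set_a, "set_a"),
                 if (!is.null(set_b)) network_name(set_b, "set_b")),
    type = if (is.null(set_b)) "within" else "between",
    effect = unname(fit$beta),
    statistic = unname(fit$t),
    df = c(1L, fit$df),
    p = unname(fit$p),
    contributing_edges = contrib),
    class = "fnc_result")
}

#' Data-driven network definition by hierarchical clustering
#'
#' Regions are clustered on their connectivity profiles (rows of the
#' group-mean matrix, diagonal masked) with distance 1 - Pearson
#' correlation and average linkage, cut at \code{k} clusters. Regions are
#' canonically ordered by label before clustering, so the result is
#' invariant to the input row order.
#'
#' @param group_mean_conn \code{conn_matrix} or symmetric matrix with
#'   dimnames.
#' @param k number of networks (2 <= k <= R).
#' @return List of [network_def()] objects (source "clustered"), ordered
#'   by first member region.
#' @export
cluster_networks <- function(group_mean_conn, k) {
  M <- conn_values(group_mean_conn)
  labels <- rownames(M)
  if (is.null(labels)) labels <- paste0("region_", seq_len(nrow(M)))
  R <- nrow(M)
  if (k > R) stop("k exceeds the number of regions")
  if (k < 2L) stop("k must be at least 2")
  ord <- order(labels)
  M <- M[ord, ord, drop = FALSE]
  labels <- labels[ord]
  diag(M) <- NA_real_
  cc <- suppressWarnings(stats::cor(t(M), use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, k = k)
  lapply(seq_len(k), function(g) {
    network_def(sprintf("cluster_%02d", g), labels[cl == g],
                source = "clustered", region_table = NULL)
  })
}

#' All within- and between-network set-level tests with FDR
#'
#' Runs [fnc_test()] for each network (within) and each pair of networks
#' (between), k(k+1)/2 tests in total, and applies Benjamini-Hochberg
#' correction across them.
#'
#' @param conn_stack,design see [fnc_test()].
#' @param networks list of [network_def()] objects.
#' @param q FDR level.
#' @param alternative sidedness.
#' @return data.frame with one row per test (network_a, network_b, type,
#'   effect, statistic, df, p, p_fdr, significant); the full
#'   \code{fnc_result} objects are attached as attribute
#'   \code{results}.
#' @export
fnc_all_pairs <- function(conn_stack, design, networks, q = 0.05,
                          alternative = "two.sided") {
  if (length(networks) < 2L) stop("need at least 2 networks")
  specs <- list()
  for (i in seq_along(networks)) {
    specs[[length(specs) + 1L]] <- list(a = i, b = NA_integer_)
  }
  for (i in seq_len(length(networks) - 1L)) {
    for (j in seq(i + 1L, length(networks))) {
      specs[[length(specs) + 1L]] <- list(a = i, b = j)
    }
  }
  results <- lapply(specs, function(sp) {
    fnc_test(conn_stack, design, networks[[sp$a]],
             if (is.na(sp$b)) NULL else networks[[sp$b]],
             alternative = alternative)
  })
  p <- vapply(results, function(r) r$p, numeric(1))
  adj <- fdr_bh(p, q)
  out <- data.frame(
    network_a = vapply(results, function(r) r$networks[1L], character(1)),
    network_b = vapply(results, function(r) {
      if (r$type == "between") r$networks[2L] else NA_character_
    }, character(1)),
    type = vapply(results, function(r) r$type, character(1)),
    effect = vapply(results, function(r) r$effect, numeric(1)),
    statistic = vapply(results, function(r) r$statistic, numeric(1)),
    df = vapply(results, function(r) r$df[2L], numeric(1)),
    p = p,
    p_fdr = adj$p_adjusted,
    significant = adj$reject,
    stringsAsFactors = FALSE)
  attr(out, "results") <- results
  out
}

#' ROI-level seed connectivity profile
#'
#' One GLM per seed-target edge with Benjamini-Hochberg correction across
#' the R - 1 targets; supports one-sided verification mode for directed
#' re-tests in other datasets.
#'
#' @param conn_stack,design see [fnc_test()].
#' @param seed_region seed region name.
#' @param q FDR level.
#' @param alternative "two.sided", "greater" or "less".
#' @return data.frame (target, effect, t, p, p_fdr, significant) with the
#'   residual df as attribute \code{df}.
#' @export
seed_profile <- function(conn_stack, design, seed_region, q = 0.05,
                         alternative = "two.sided") {
  labels <- attr(conn_stack, "region_labels")
  s <- match(seed_region, labels)
  if (is.na(s)) stop("unknown seed region: ", seed_region)
  targets <- setdiff(seq_along(labels), s)
  cols <- edge_column(rep(s, length(targets)), targets)
  ad <- align_stack_design(conn_stack, design)
  fit <- ols_t(ad$X, ad$Y[, cols, drop = FALSE],
               attr(design, "focus"), alternative)
  adj <- fdr_bh(fit$p, q)
  out <- data.frame(target = labels[targets],
                    effect = unname(fit$beta),
                    t = unname(fit$t),
                    p = unname(fit$p),
                    p_fdr = adj$p_adjusted,
                    significant = adj$reject,
                    stringsAsFactors = FALSE)
  attr(out, "df") <- fit$df
  out
}
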