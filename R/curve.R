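#' @name ranked_similarity
#' @title Expression-ranked nested-submatrix correlation curves
#' @description The package's core statistic: the Pearson correlation
#'   between the lower triangles of two region-by-region effect matrices,
#'   recomputed over nested submatrices obtained by iteratively removing
#'   the region with the lowest marker-gene expression until three
#'   regions remain; the area under the resulting curve (AUC) is
#'   calibrated by permutation of the genotype labels.
NULL

# Resolve a ranking (region_profile data.frame or named rank vector)
# against the matrix labels. Returns the kept labels (in matrix order)
# and their rank positions (1 = highest expression).
ranking_positions <- function(ranking, labels) {
  if (is.data.frame(ranking)) {
    if (!all(c("region", "rank") %in% names(ranking))) {
      stop("ranking data.frame needs 'region' and 'rank' columns")
    }
    if ("supported" %in% names(ranking)) {
      ranking <- ranking[ranking$supported, , drop = FALSE]
    }
    ranks <- stats::setNames(ranking$rank, ranking$region)
  } else if (is.numeric(ranking) && !is.null(names(ranking))) {
    ranks <- ranking
  } else {
    stop("ranking must be a region profile or a named rank vector")
  }
  keep <- labels[labels %in% names(ranks)]
  missing_all <- setdiff(labels, names(ranks))
  if (is.data.frame(ranking) == FALSE && length(missing_all) > 0L) {
    stop("ranking does not cover region(s): ",
         paste(utils::head(missing_all, 5L), collapse = ", "))
  }
  if (length(keep) < 3L) stop("fewer than 3 ranked regions available")
  pos <- rank(ranks[keep], ties.method = "first")
  list(keep = keep, pos = stats::setNames(as.integer(pos), keep))
}

# r over nested prefixes. x and y must be ordered so the first s(s-1)/2
# entries are exactly the edges of the top-s submatrix; cumulative sums
# (long-double accumulators) then give every submatrix correlation in
# one pass.
prefix_curve_r <- function(x, y, R_full, min_size = 3L) {
  Sx <- cumsum(x); Sy <- cumsum(y)
  Sxx <- cumsum(x * x); Syy <- cumsum(y * y); Sxy <- cumsum(x * y)
  sizes <- seq(R_full, min_size)
  nE <- sizes * (sizes - 1) / 2
  vx <- Sxx[nE] - Sx[nE]^2 / nE
  vy <- Syy[nE] - Sy[nE]^2 / nE
  cxy <- Sxy[nE] - Sx[nE] * Sy[nE] / nE
  degen <- (vx <= 1e-12 * pmax(Sxx[nE], 1e-300)) |
    (vy <= 1e-12 * pmax(Syy[nE], 1e-300))
  denom <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  r <- ifelse(degen | denom == 0, 0, cxy / denom)
  r <- pmin(pmax(r, -1), 1)
  list(sizes = as.integer(sizes), n_edges = as.integer(round(nE)),
       r = r, degenerate = degen)
}

# Precompute the matrix-extraction index that orders the kept-region
# edges by the size of the smallest nested submatrix containing them.
curve_edge_plan <- function(ranking, labels) {
  rp <- ranking_positions(ranking, labels)
  K <- length(rp$keep)
  kidx <- match(rp$keep, labels)
  ei <- lower_edge_index(K)
  m <- pmax(rp$pos[rp$keep][ei$i], rp$pos[rp$keep][ei$j])
  ord <- order(m)
  list(keep = rp$keep, R_full = K,
       extract = cbind(kidx[ei$i[ord]], kidx[ei$j[ord]]))
}

#' Correlation curve between two effect matrices over expression-ranked
#' nested submatrices
#'
#' Regions are sorted by expression rank (1 = highest). Starting from the
#' full matrix, the lowest-ranked region is removed one at a time until
#' three remain; at each size the lower triangles of both submatrices are
#' Pearson-correlated. The AUC is the discrete unit-spacing sum of the
#' correlations (switchable to the trapezoid rule, which differs only in
#' the endpoint weights).
#'
#' A submatrix whose edge vector is (numerically) constant gets r = 0 and
#' is flagged, with a warning, so degenerate inputs cannot crash the
#' curve.
#'
#' @param effect_a,effect_b \code{effect_matrix} objects (or symmetric
#'   matrices with identical dimnames) sharing region labels and order.
#' @param ranking a region expression profile (see [build_profiles()]) or
#'   a named rank vector covering the matrix regions; unsupported profile
#'   regions are excluded.
#' @param min_size smallest submatrix size (default 3).
#' @param auc_rule "sum" (default) or "trapezoid".
#' @param contrast_name label stored in the result.
#' @return Object of class \code{correlation_curve}: list with
#'   \code{sizes} (descending), \code{n_edges}, \code{r_values},
#'   \code{auc}, \code{auc_rule}, \code{degenerate},
#'   \code{contrast_name}.
#' @export
correlation_curve <- function(effect_a, effect_b, ranking,
                              min_size = 3L, auc_rule = c("sum", "trapezoid"),
                              contrast_name = NULL) {
  auc_rule <- match.arg(auc_rule)
  if (min_size < 3L) stop("min_size must be at least 3")
  A <- conn_values(effect_a)
  B <- conn_values(effect_b)
  labels <- rownames(A)
  if (is.null(labels)) labels <- paste0("region_", seq_len(nrow(A)))
  labs_b <- rownames(B)
  if (!is.null(labs_b) && !identical(labels, labs_b)) {
    stop("effect matrices must share region labels and order")
  }
  if (!all(dim(A) == dim(B))) stop("effect matrices differ in size")
  plan <- curve_edge_plan(ranking, labels)
  if (plan$R_full < min_size) stop("fewer ranked regions than min_size")
  res <- prefix_curve_r(A[plan$extract], B[plan$extract],
                        plan$R_full, min_size)
  if (any(res$degenerate)) {
    warning("zero-variance edge vector at ",
            sum(res$degenerate), " curve size(s); r recorded as 0")
  }
  auc <- curve_auc_value(res$r, auc_rule)
  if (is.null(contrast_name)) {
    contrast_name <- if (inherits(effect_b, "effect_matrix")) {
      effect_b$contrast_name
    } else {
      ""
    }
  }
  structure(list(sizes = res$sizes, n_edges = res$n_edges,
                 r_values = res$r, auc = auc, auc_rule = auc_rule,
                 degenerate = res$degenerate,
                 contrast_name = contrast_name),
            class = "correlation_curve")
}

curve_auc_value <- function(r, auc_rule) {
  if (auc_rule == "sum") {
    sum(r)
  } else {
    sum(r) - (r[1L] + r[length(r)]) / 2
  }
}

#' Permutation p-value with the add-one estimator
#'
#' \code{(1 + #\{null at or beyond observed\}) / (1 + n_perm)}; the
#' add-one rule avoids p = 0 from a finite permutation sample.
#'
#' @param observed observed statistic.
#' @param null vector of null statistics.
#' @param direction "greater" (null >= observed counts as beyond) or
#'   "less".
#' @return p-value in (0, 1].
#' @export
perm_pvalue <- function(observed, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  extreme <- if (direction == "greater") sum(null >= observed)
             else sum(null <= observed)
  (1 + extreme) / (1 + length(null))
}

default_curve_directions <- function(contrasts) {
  map <- c(ket_gt_pla = "greater", ket_gt_mdz = "greater",
           mdz_gt_pla = "less", snp = "greater", sz_gt_hc = "greater")
  unknown <- setdiff(contrasts, names(map))
  if (length(unknown) > 0L) {
    stop("no default direction for contrast(s) ",
         paste(unknown, collapse = ", "),
         "; supply `directions` explicitly")
  }
  map[contrasts]
}

#' Genotype-permutation test for correlation-curve AUCs
#'
#' For each permutation the allele-count column of the design is shuffled
#' across patients (gender and dose stay with their subject), the
#' per-edge GLM is refit, and the full correlation curve and AUC against
#' each fixed pharmacological effect matrix are recomputed. The p-value
#' counts null AUCs at or beyond the observed one in the stated direction
#' (add-one estimator); Benjamini-Hochberg FDR is applied across the
#' contrasts.
#'
#' @param conn_stack patients x edges matrix ([stack_connectivity()]).
#' @param design design matrix with the allele column as focus
#'   ([make_design()]).
#' @param pharm_effects named list of fixed \code{effect_matrix} objects
#'   (one per pharmacological contrast).
#' @param ranking region expression ranking (see [correlation_curve()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed; the null distribution is reproducible from it.
#' @param directions named character vector of test directions per
#'   contrast ("greater"/"less"); defaults cover the standard contrast
#'   names (ketamine-positive contrasts greater, mdz_gt_pla less).
#' @param auc_rule passed to the curve computation.
#' @return Named list (per contrast) of \code{permutation_result}
#'   objects: \code{observed_auc}, \code{observed_curve},
#'   \code{null_aucs}, \code{direction}, \code{p_raw}, \code{p_fdr},
#'   \code{n_perm}, \code{seed}.
#' @export
permutation_test <- function(conn_stack, design, pharm_effects, ranking,
                             n_perm = 10000L, seed = 1L,
                             directions = NULL,
                             auc_rule = c("sum", "trapezoid")) {
  auc_rule <- match.arg(auc_rule)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (length(pharm_effects) == 0L) stop("no pharmacological contrasts")
  contrasts <- names(pharm_effects)
  if (is.null(contrasts) || any(contrasts == "")) {
    stop("pharm_effects must be a named list")
  }
  if (is.null(directions)) {
    directions <- default_curve_directions(contrasts)
  }
  directions <- directions[contrasts]
  if (any(is.na(directions))) stop("missing direction for some contrast")

  labels <- attr(conn_stack, "region_labels")
  observed_fit <- fit_edge_glm(conn_stack, design)
  ad <- align_stack_design(conn_stack, design)
  design <- ad$X
  conn_stack <- ad$Y
  plan <- curve_edge_plan(ranking, labels)
  yb <- lapply(pharm_effects, function(e) {
    M <- conn_values(e)
    if (!identical(rownames(M), labels)) {
      stop("pharmacological effect matrices must share the genetic ",
           "matrix's region labels")
    }
    M[plan$extract]
  })

  observed <- lapply(contrasts, function(cn) {
    correlation_curve(observed_fit, pharm_effects[[cn]], ranking,
                      auc_rule = auc_rule, contrast_name = cn)
  })
  names(observed) <- contrasts

  X <- design
  focus <- attr(design, "focus")
  k <- match(focus, colnames(X))
  n <- nrow(X)
  null_aucs <- matrix(NA_real_, n_perm, length(contrasts),
                      dimnames = list(NULL, contrasts))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    Xp <- X
    Xp[, k] <- X[sample.int(n), k]
    beta <- solve(crossprod(Xp), crossprod(Xp, conn_stack))[k, ]
    M <- fill_symmetric(beta, labels)
    xa <- M[plan$extract]
    for (ci in seq_along(contrasts)) {
      res <- prefix_curve_r(xa, yb[[ci]], plan$R_full)
      null_aucs[b, ci] <- curve_auc_value(res$r, auc_rule)
    }
  }
  p_raw <- vapply(seq_along(contrasts), function(ci) {
    perm_pvalue(observed[[ci]]$auc, null_aucs[, ci], directions[[ci]])
  }, numeric(1))
  p_fdr <- stats::p.adjust(p_raw, method = "BH")
  out <- lapply(seq_along(contrasts), function(ci) {
    structure(list(
      contrast_name = contrasts[[ci]],
      observed_auc = observed[[ci]]$auc,
      observed_curve = observed[[ci]],
      null_aucs = null_aucs[, ci],
      direction = unname(directions[[ci]]),
      p_raw = p_raw[[ci]],
      p_fdr = p_fdr[[ci]],
      n_perm = as.integer(n_perm),
      seed = as.integer(seed)),
      class = "permutation_result")
  })
  names(out) <- contrasts
  out
}

#' Benjamini-Hochberg FDR adjustment with rejection flags
#'
#' @param p_values vector of p-values in (0, 1].
#' @param q FDR level.
#' @return List with \code{p_adjusted} and logical \code{reject}.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0) ||
      any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}
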