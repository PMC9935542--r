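#' Convert a single-hypothesis Wilks lambda to an exact F statistic
#'
#' For a hypothesis with a single degree of freedom, Rao's transformation
#' is exact: F = ((1 - Lambda) / Lambda) * ((v_e - p + 1) / p) on
#' (p, v_e - p + 1) degrees of freedom, where p is the number of response
#' variables and v_e the error degrees of freedom.
#'
#' @param lambda Wilks lambda in (0, 1].
#' @param p_responses number of response variables.
#' @param error_df error degrees of freedom v_e.
#' @return List with \code{F}, \code{df1}, \code{df2}, \code{p}.
#' @examples
#' wilks_to_f(0.923, 3, 141)  # F ~ 3.9 on (3, 139)
#' @export
wilks_to_f <- function(lambda, p_responses, error_df) {
  if (!is.finite(lambda) || lambda <= 0 || lambda > 1) {
    stop("lambda must lie in (0, 1]")
  }
  df1 <- p_responses
  df2 <- error_df - p_responses + 1
  if (df2 <= 0) stop("error_df too small for ", p_responses, " responses")
  F <- ((1 - lambda) / lambda) * (df2 / df1)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Multivariate GLM (Wilks lambda) for one symptom domain
#'
#' Tests the single-df hypothesis that the predictor of interest (the
#' C-allele count) has no effect on the domain's subcategory sum scores,
#' with the design's covariates partialled out. Lambda is computed from
#' the residual SSCP matrices of the full and reduced models:
#' Lambda = det(E) / det(E + H).
#'
#' @param scores n x p numeric matrix of subcategory sums (row names are
#'   matched against design row names when both are present).
#' @param design design matrix with \code{focus} attribute
#'   ([make_design()]).
#' @return List with \code{wilks_lambda}, \code{F}, \code{df1},
#'   \code{df2}, \code{p}, \code{error_df}, \code{n}.
#' @export
domain_manova <- function(scores, design) {
  scores <- as.matrix(scores)
  ad <- align_stack_design(scores, design)
  Y <- ad$Y; X <- ad$X
  n <- nrow(Y); p <- ncol(Y)
  focus <- attr(design, "focus")
  k <- match(focus, colnames(X))
  if (is.na(k)) stop("focus column '", focus, "' not in design")
  if (n <= p + ncol(X) + 1L) stop("too few subjects for the MANOVA")
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X)) stop("rank-deficient design")
  E <- crossprod(qr.resid(qr_full, Y))
  X0 <- X[, -k, drop = FALSE]
  E0 <- crossprod(qr.resid(qr(X0), Y))
  H <- E0 - E
  det_E <- det(E); det_EH <- det(E + H)
  if (!is.finite(det_E) || det_E <= 0 || det_EH <= 0) {
    stop("singular residual covariance")
  }
  lambda <- det_E / det_EH
  lambda <- min(lambda, 1)
  v_e <- n - qr_full$rank
  f <- wilks_to_f(lambda, p, v_e)
  list(wilks_lambda = lambda, F = f$F, df1 = f$df1, df2 = f$df2,
       p = f$p, error_df = v_e, n = n)
}

#' Partial correlation of two variables given covariates
#'
#' Pearson correlation of the OLS residuals of x and y on an intercept
#' plus the covariates; df = n - c - 2.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of c covariates, or NULL
#'   for the plain correlation.
#' @param alternative sidedness of the p-value.
#' @return List with \code{r}, \code{df}, \code{p}.
#' @export
partial_corr <- function(x, y, covariates = NULL,
                         alternative = "two.sided") {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1L)
    c_cov <- 0L
  } else {
    Z <- cbind(1, as.matrix(covariates))
    c_cov <- ncol(Z) - 1L
  }
  if (n <= c_cov + 2L) stop("too few observations (need n > c + 2)")
  qz <- qr(Z)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (sum(rx^2) <= 1e-20 * max(1, sum(x^2)) ||
      sum(ry^2) <= 1e-20 * max(1, sum(y^2))) {
    stop("zero residual variance; partial correlation undefined")
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  r <- min(max(r, -1), 1)
  df <- n - c_cov - 2L
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df),
              stop("unknown alternative"))
  list(r = r, df = df, p = min(max(p, .Machine$double.xmin), 1))
}

#' Symptom-domain association tests with post-hoc partial correlations
#'
#' Runs the per-domain multivariate GLM for the allele-count hypothesis
#' with FDR across domains, plus post-hoc partial correlations (allele
#' count vs each subcategory sum, corrected for the design covariates)
#' with FDR across the domain's subcategories.
#'
#' @param symptoms symptom table ([simulate_symptoms()]).
#' @param cohort cohort table.
#' @param domains named list of subcategory columns per domain.
#' @param allele_model,covariates passed to [make_design()].
#' @param q FDR level.
#' @return Named list per domain: the [domain_manova()] result plus
#'   \code{p_fdr} and \code{partial_r} (data.frame subcategory, r, df,
#'   p, p_fdr).
#' @export
symptom_domain_tests <- function(symptoms, cohort,
                                 domains = symptom_domains(),
                                 allele_model = "additive",
                                 covariates = c("gender", "dose"),
                                 q = 0.05) {
  design <- make_design(cohort, predictor = "allele",
                        allele_model = allele_model,
                        covariates = covariates)
  rows <- match(rownames(design), symptoms$subject_id)
  if (any(is.na(rows))) stop("symptoms missing for some designed subjects")
  allele <- design[, attr(design, "focus")]
  Z <- design[, setdiff(colnames(design), c("intercept",
                                            attr(design, "focus"))),
              drop = FALSE]
  out <- lapply(domains, function(cols) {
    sc <- as.matrix(symptoms[rows, cols, drop = FALSE])
    rownames(sc) <- rownames(design)
    res <- domain_manova(sc, design)
    pr <- lapply(cols, function(cl) {
      partial_corr(allele, sc[, cl], Z)
    })
    res$partial_r <- data.frame(
      subcategory = cols,
      r = vapply(pr, function(v) v$r, numeric(1)),
      df = vapply(pr, function(v) v$df, numeric(1)),
      p = vapply(pr, function(v) v$p, numeric(1)),
      stringsAsFactors = FALSE)
    res$partial_r$p_fdr <- fdr_bh(res$partial_r$p, q)$p_adjusted
    res
  })
  p_dom <- vapply(out, function(r) r$p, numeric(1))
  adj <- fdr_bh(p_dom, q)
  for (i in seq_along(out)) {
    out[[i]]$p_fdr <- adj$p_adjusted[[i]]
    out[[i]]$significant <- adj$reject[[i]]
  }
  out
}

#' Partial correlation of selected edges with a symptom score
#'
#' For edges pre-selected by their genotype association (e.g. from
#' [seed_profile()]), correlates each edge's connectivity with the
#' symptom sum, given covariates, with Benjamini-Hochberg correction
#' across the selected edges.
#'
#' @param edge_stack n x m matrix of selected edge connectivities
#'   (columns named by edge).
#' @param scores numeric symptom sum per subject.
#' @param covariates covariate matrix or NULL.
#' @param q FDR level.
#' @param alternative sidedness.
#' @return data.frame (edge, r, df, p, p_fdr, significant).
#' @export
edge_symptom_coupling <- function(edge_stack, scores, covariates = NULL,
                                  q = 0.05, alternative = "two.sided") {
  edge_stack <- as.matrix(edge_stack)
  m <- ncol(edge_stack)
  res <- lapply(seq_len(m), function(e) {
    partial_corr(edge_stack[, e], scores, covariates, alternative)
  })
  p <- vapply(res, function(v) v$p, numeric(1))
  adj <- fdr_bh(p, q)
  data.frame(
    edge = colnames(edge_stack) %||% paste0("edge_", seq_len(m)),
    r = vapply(res, function(v) v$r, numeric(1)),
    df = vapply(res, function(v) v$df, numeric(1)),
    p = p,
    p_fdr = adj$p_adjusted,
    significant = adj$reject,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
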