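#' Build a second-level design matrix
#'
#' The predictor of interest is either the C-allele count (additive
#' genetic model; optionally recoded to minor-allele presence for the
#' exploratory dominant model) or a patient-vs-control group indicator.
#' Gender and haloperidol-equivalent dose enter as predictors of no
#' interest. Rows with missing values in any used column are dropped.
#'
#' @param cohort cohort table (see [simulate_cohort()]).
#' @param predictor "allele" (patients only) or "group"
#'   (patients + controls, indicator patient = 1).
#' @param allele_model "additive" (0/1/2) or "dominant" ({0} -> 0,
#'   {1,2} -> 1).
#' @param covariates columns of \code{cohort} used as nuisance
#'   regressors.
#' @return Numeric design matrix with an intercept column, subject ids as
#'   row names, and attribute \code{focus} naming the column of interest.
#' @export
make_design <- function(cohort, predictor = c("allele", "group"),
                        allele_model = c("additive", "dominant"),
                        covariates = c("gender", "dose")) {
  predictor <- match.arg(predictor)
  allele_model <- match.arg(allele_model)
  if (predictor == "allele") {
    rows <- cohort$group == "patient" & !is.na(cohort$allele_count)
    x <- cohort$allele_count[rows]
    if (allele_model == "dominant") x <- as.integer(x > 0)
    focus <- "allele"
  } else {
    rows <- cohort$group %in% c("patient", "control")
    x <- as.integer(cohort$group[rows] == "patient")
    focus <- "group"
  }
  X <- cbind(intercept = 1, x)
  colnames(X)[2L] <- focus
  for (cv in covariates) {
    X <- cbind(X, cohort[[cv]][rows])
    colnames(X)[ncol(X)] <- cv
  }
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  rownames(X) <- cohort$subject_id[rows][keep]
  attr(X, "focus") <- focus
  X
}

# Core vectorized OLS: coefficient of the focus column, t and two-sided p
# per response column. Guards exact fits (residual variance 0) by
# flooring p at the smallest positive double.
ols_t <- function(X, Y, focus, alternative = "two.sided") {
  n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  df <- n - qrX$rank
  if (df < 1L) stop("no residual degrees of freedom")
  coef <- qr.coef(qrX, Y)
  fitted <- X %*% coef
  rss <- colSums((Y - fitted)^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  k <- match(focus, colnames(X))
  if (is.na(k)) stop("focus column '", focus, "' not in design")
  se <- sqrt(pmax(rss / df, 0) * XtXinv[k, k])
  beta <- coef[k, ]
  t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df),
              stop("unknown alternative"))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(beta = beta, t = t, p = p, df = df, coef = coef)
}

#' Per-edge general linear model
#'
#' Fits the same OLS design to every connectivity edge (columns of the
#' stacked subjects x edges matrix) and reports the coefficient of the
#' predictor of interest with its t statistic and p-value
#' (df = n - rank(X)).
#'
#' @param conn_stack subjects x edges matrix from [stack_connectivity()];
#'   row names are matched against design row names when both exist.
#' @param design design matrix from [make_design()] (or any numeric
#'   matrix with attribute \code{focus}).
#' @param contrast_name label stored in the result.
#' @param alternative "two.sided" (default), "greater", or "less";
#'   one-sided p-values support directional verification re-tests.
#' @return Object of class \code{effect_matrix}: region-by-region
#'   \code{effect}, \code{t}, \code{p} matrices (diagonal masked as 0 for
#'   effect/t and 1 for p), plus \code{df}, \code{contrast_name},
#'   \code{alternative}.
#' @export
fit_edge_glm <- function(conn_stack, design,
                         contrast_name = attr(design, "focus"),
                         alternative = "two.sided") {
  labels <- attr(conn_stack, "region_labels")
  if (is.null(labels)) stop("conn_stack lacks region_labels attribute")
  ad <- align_stack_design(conn_stack, design)
  if (nrow(ad$X) <= ncol(ad$X) + 2L) {
    stop("too few subjects for the design (need n > n_columns + 2)")
  }
  fit <- ols_t(ad$X, ad$Y, attr(ad$X, "focus"), alternative)
  structure(list(
    region_labels = labels,
    effect = fill_symmetric(fit$beta, labels),
    t = fill_symmetric(fit$t, labels),
    p = fill_symmetric(fit$p, labels, diag_value = 1),
    df = fit$df,
    contrast_name = contrast_name,
    alternative = alternative),
    class = "effect_matrix")
}

#' Pharmacological contrast specifications
#'
#' Signed combinations of the six crossover sessions. Each drug contrast
#' takes the within-condition post - pre difference before the
#' between-condition subtraction, so session-constant offsets cancel:
#' e.g. ketamine > placebo is
#' (ketamine post - ketamine pre) - (placebo post - placebo pre).
#'
#' @param name one of "ket_gt_pla", "mdz_gt_pla", "ket_gt_mdz".
#' @return Object of class \code{contrast_spec} with \code{name} and the
#'   named session \code{weights}.
#' @export
contrast_spec <- function(name = c("ket_gt_pla", "mdz_gt_pla",
                                   "ket_gt_mdz")) {
  name <- match.arg(name)
  weights <- switch(name,
    ket_gt_pla = c(ketamine_post = 1, ketamine_pre = -1,
                   placebo_post = -1, placebo_pre = 1),
    mdz_gt_pla = c(midazolam_post = 1, midazolam_pre = -1,
                   placebo_post = -1, placebo_pre = 1),
    ket_gt_mdz = c(ketamine_post = 1, ketamine_pre = -1,
                   midazolam_post = -1, midazolam_pre = 1))
  structure(list(name = name, weights = weights), class = "contrast_spec")
}

#' Compute per-session connectivity matrices grouped by subject
#'
#' @param ts_set \code{roi_ts_set} from [simulate_timeseries()] (or an
#'   equivalently shaped list).
#' @param subjects optional subject filter.
#' @return Named list: subject -> named list session -> conn_matrix.
#' @export
connectivity_by_session <- function(ts_set, subjects = NULL) {
  idx <- ts_set$index
  if (!is.null(subjects)) idx <- idx[idx$subject_id %in% subjects, ]
  out <- list()
  for (r in seq_len(nrow(idx))) {
    sub <- idx$subject_id[r]
    if (is.null(out[[sub]])) out[[sub]] <- list()
    out[[sub]][[idx$session[r]]] <-
      compute_connectivity(ts_set$series[[idx$key[r]]],
                           ts_set$region_labels)
  }
  out
}

#' Paired within-subject pharmacological contrast
#'
#' Per subject, combines the session connectivity matrices with the
#' contrast weights; the effect is the subject mean and inference is the
#' paired t-test (df = n - 1) per edge.
#'
#' @param conn_by_session list subject -> named list session ->
#'   \code{conn_matrix} (see [connectivity_by_session()]).
#' @param spec a [contrast_spec()].
#' @param alternative sidedness of the p-values.
#' @return \code{effect_matrix} (effect = mean paired contrast).
#' @export
paired_contrast <- function(conn_by_session, spec,
                            alternative = "two.sided") {
  stopifnot(inherits(spec, "contrast_spec"))
  need <- names(spec$weights)
  n <- length(conn_by_session)
  if (n < 2L) stop("need at least 2 subjects for a paired contrast")
  labels <- NULL
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    subj <- names(conn_by_session)[s]
    have <- conn_by_session[[s]]
    miss <- setdiff(need, names(have))
    if (length(miss) > 0L) {
      stop("subject ", subj, " is missing session(s): ",
           paste(miss, collapse = ", "))
    }
    if (is.null(labels)) labels <- have[[need[1L]]]$region_labels
    d <- 0
    for (sess in need) d <- d + spec$weights[[sess]] * have[[sess]]$z
    rows[[s]] <- vectorize_lower(d)
  }
  D <- do.call(rbind, rows)
  effect <- colMeans(D)
  sdv <- apply(D, 2L, stats::sd)
  se <- sdv / sqrt(n)
  t <- ifelse(se > 0, effect / se,
              ifelse(effect == 0, 0, sign(effect) * Inf))
  df <- n - 1L
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  structure(list(
    region_labels = labels,
    effect = fill_symmetric(effect, labels),
    t = fill_symmetric(t, labels),
    p = fill_symmetric(p, labels, diag_value = 1),
    df = df,
    contrast_name = spec$name,
    alternative = alternative),
    class = "effect_matrix")
}

#' Levene's test for homogeneity of variance (mean-centered variant)
#'
#' One-way ANOVA on the absolute deviations from the group means.
#'
#' @param values numeric vector.
#' @param group group membership (coerced to factor).
#' @return List with \code{W}, \code{df1}, \code{df2}, \code{p}.
#' @export
levene_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("each group needs n >= 2")
  d <- abs(values - stats::ave(values, group))
  a <- stats::anova(stats::lm(d ~ group))
  W <- a[["F value"]][1L]
  if (is.na(W)) W <- 0
  p <- a[["Pr(>F)"]][1L]
  if (is.na(p)) p <- 1
  list(W = W, df1 = a$Df[1L], df2 = a$Df[2L], p = p)
}
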