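# Shared fixtures and independent oracles, built in code at test time.

# random symmetric matrix with a masked diagonal and region names
rand_sym <- function(R, seed, labels = paste0("r", seq_len(R))) {
  set.seed(seed)
  m <- matrix(rnorm(R * R), R, R)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# Brute-force correlation-curve oracle: re-sorts, re-slices and
# re-correlates each nested submatrix independently (lower triangle
# extracted with explicit loops, independent of the package's ordering).
oracle_curve <- function(A, B, ranks, min_size = 3L) {
  ord <- names(sort(ranks))
  R <- length(ord)
  sizes <- seq(R, min_size)
  r <- vapply(sizes, function(s) {
    sub <- ord[seq_len(s)]
    va <- vb <- numeric(0)
    for (i in seq_len(s)) {
      for (j in seq_len(s)) {
        if (i > j) {
          va <- c(va, A[sub[i], sub[j]])
          vb <- c(vb, B[sub[i], sub[j]])
        }
      }
    }
    stats::cor(va, vb)
  }, numeric(1))
  list(sizes = sizes, r = r, auc = sum(r))
}

# Gaussian subjects-by-edges stack with the attributes the second-level
# functions expect (edge-level null data for calibration-style tests).
gauss_stack <- function(n, labels, seed, sd = 1, ids = sprintf("S%03d", seq_len(n))) {
  set.seed(seed)
  R <- length(labels)
  Y <- matrix(rnorm(n * R * (R - 1) / 2, sd = sd), nrow = n)
  rownames(Y) <- ids
  attr(Y, "region_labels") <- labels
  attr(Y, "edge_index") <- lower_edge_index(R)
  Y
}

# design matrix with an allele focus column drawn from HWE
allele_design <- function(n, seed, p = 0.277, covariates = TRUE,
                          ids = sprintf("S%03d", seq_len(n))) {
  set.seed(seed)
  allele <- sample(0:2, n, replace = TRUE,
                   prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  X <- if (covariates) {
    cbind(intercept = 1, allele = allele,
          gender = rbinom(n, 1, 0.5),
          dose = pmin(rgamma(n, 2, scale = 3), 30))
  } else {
    cbind(intercept = 1, allele = allele)
  }
  rownames(X) <- ids
  attr(X, "focus") <- "allele"
  X
}

# stack the resting-state connectivity of one cohort group
stack_group <- function(ts, cohort, groups = "patient") {
  ids <- cohort$subject_id[cohort$group %in% groups]
  keys <- paste0(ids, ".rest")
  cl <- lapply(keys, function(k) {
    compute_connectivity(ts$series[[k]], ts$region_labels)
  })
  names(cl) <- ids
  stack_connectivity(cl)
}

# column index of edge (a, b) given the stack's labels
edge_col_of <- function(stack, a, b) {
  labels <- attr(stack, "region_labels")
  i <- match(c(a, b), labels)
  hi <- max(i); lo <- min(i)
  (hi - 1L) * (hi - 2L) / 2L + lo
}
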