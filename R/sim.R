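#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the synthetic cohort/time-series/symptom
#' generator. Defaults reproduce the statistical structure of the study
#' the package is designed for: 146 patients genotyped at a SNP with
#' C-allele frequency 27.7% under Hardy-Weinberg equilibrium, 142
#' controls, and a 28-subject three-way crossover pharmaco-fMRI arm
#' (ketamine / midazolam / placebo, pre and post infusion), on a
#' 106-region parcellation.
#'
#' Effects are planted as additive perturbations of the region-by-region
#' correlation matrix, confined to edges among \code{signal_regions}:
#' patients receive \code{allele_count * allele_effect}, pharmaco post
#' sessions receive \code{ket_effect} or \code{mdz_effect}. Perturbed
#' matrices are projected to the nearest valid correlation matrix
#' (eigenvalue clipping at 1e-6 plus diagonal renormalization), which
#' keeps planted effects approximately linear in allele count for small
#' perturbations. \code{signal_weights} optionally grades the
#' perturbation across signal regions (the edge between regions i and j
#' is perturbed by \code{delta * w_i * w_j}), emulating effects whose
#' magnitude tracks regional marker-gene expression.
#'
#' @param seed integer RNG seed; the whole synthetic dataset is
#'   reproducible bit-exactly from it.
#' @param n_patients,n_controls,n_pharmaco cohort sizes.
#' @param allele_freq C-allele frequency in (0,1), used for HWE genotype
#'   sampling.
#' @param n_timepoints BOLD-like time-series length T (>= 10).
#' @param region_labels character vector of region names (default: the
#'   full 106-region table).
#' @param signal_regions subset of \code{region_labels} carrying planted
#'   effects.
#' @param signal_weights optional numeric vector of per-region weights,
#'   same length/order as \code{signal_regions}; default all 1.
#' @param allele_effect,ket_effect,mdz_effect correlation-scale
#'   perturbations per C-allele / for the ketamine post sessions / for
#'   the midazolam post sessions.
#' @param base_cor baseline off-diagonal correlation among all regions.
#' @param noise_sd marginal standard deviation of the simulated series.
#' @param never_medicated_frac fraction of patients with dose 0.
#' @param symptom_items items per symptom subcategory (each item is a
#'   bipolar -1/0/+1 rating, so subcategory sums live in
#'   [-symptom_items, symptom_items]).
#' @param symptom_intercept,symptom_allele_slope,symptom_edge_slope,symptom_noise_sd
#'   parameters of the planted qualitative-language coupling:
#'   latent = intercept - allele_slope * allele_count
#'   + edge_slope * edge_connectivity + N(0, noise_sd).
#'   Slopes must be non-negative.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 146L,
                       n_controls = 142L,
                       n_pharmaco = 28L,
                       allele_freq = 0.277,
                       n_timepoints = 150L,
                       region_labels = default_region_table()$name,
                       signal_regions = character(0),
                       signal_weights = NULL,
                       allele_effect = 0,
                       ket_effect = 0,
                       mdz_effect = 0,
                       base_cor = 0.1,
                       noise_sd = 1,
                       never_medicated_frac = 0.1,
                       symptom_items = 7L,
                       symptom_intercept = 0,
                       symptom_allele_slope = 0,
                       symptom_edge_slope = 0,
                       symptom_noise_sd = 1) {
  if (!is.finite(allele_freq) || allele_freq < 0 || allele_freq > 1) {
    stop("allele_freq must lie in [0, 1]")
  }
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (symptom_allele_slope < 0 || symptom_edge_slope < 0) {
    stop("symptom coupling slopes must be non-negative")
  }
  if (anyDuplicated(region_labels)) stop("region_labels must be unique")
  bad <- setdiff(signal_regions, region_labels)
  if (length(bad) > 0L) {
    stop("signal_regions not in region_labels: ", paste(bad, collapse = ", "))
  }
  if (is.null(signal_weights)) {
    signal_weights <- rep(1, length(signal_regions))
  }
  if (length(signal_weights) != length(signal_regions)) {
    stop("signal_weights must match signal_regions in length")
  }
  structure(list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_pharmaco = as.integer(n_pharmaco),
    allele_freq = allele_freq,
    n_timepoints = as.integer(n_timepoints),
    region_labels = region_labels,
    signal_regions = signal_regions,
    signal_weights = signal_weights,
    allele_effect = allele_effect,
    ket_effect = ket_effect,
    mdz_effect = mdz_effect,
    base_cor = base_cor,
    noise_sd = noise_sd,
    never_medicated_frac = never_medicated_frac,
    symptom_items = as.integer(symptom_items),
    symptom_intercept = symptom_intercept,
    symptom_allele_slope = symptom_allele_slope,
    symptom_edge_slope = symptom_edge_slope,
    symptom_noise_sd = symptom_noise_sd),
    class = "sim_config")
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalues are clipped from below at \code{min_eig} and the diagonal
#' is renormalized to one. Used to make additively perturbed correlation
#' matrices positive semi-definite.
#'
#' @param m symmetric matrix with unit diagonal (approximately).
#' @param min_eig eigenvalue floor.
#' @return A valid correlation matrix.
#' @export
nearest_correlation <- function(m, min_eig = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, min_eig)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  if (any(!is.finite(out))) stop("correlation projection failed (non-finite)")
  out
}

#' Simulate a cohort table and session design
#'
#' Genotypes are drawn i.i.d. from Hardy-Weinberg proportions at
#' \code{config$allele_freq}. Patient gender is Bernoulli(0.5) (coded
#' 0 = female, 1 = male); haloperidol-equivalent dose is Gamma(shape 2,
#' scale 3) truncated at 30 mg/day, with a never-medicated fraction at
#' dose 0. Controls carry no genotype or dose; the pharmaco arm is male
#' (as in the emulated crossover study) with six sessions each
#' (ketamine/midazolam/placebo x pre/post). Deterministic given
#' \code{config$seed}.
#'
#' @param config a [sim_config()].
#' @return List with \code{cohort} (data.frame: subject_id, group,
#'   allele_count, gender, dose) and \code{sessions} (data.frame:
#'   subject_id, condition, phase, order_index, session).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$allele_freq
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)

  pat_id <- sprintf("P%03d", seq_len(config$n_patients))
  ctl_id <- sprintf("C%03d", seq_len(config$n_controls))
  phr_id <- sprintf("X%03d", seq_len(config$n_pharmaco))

  allele <- sample(0:2, config$n_patients, replace = TRUE, prob = hwe)
  gender <- stats::rbinom(config$n_patients, 1L, 0.5)
  dose <- pmin(stats::rgamma(config$n_patients, shape = 2, scale = 3), 30)
  dose[stats::runif(config$n_patients) < config$never_medicated_frac] <- 0

  cohort <- data.frame(
    subject_id = c(pat_id, ctl_id, phr_id),
    group = rep(c("patient", "control", "pharmaco"),
                c(config$n_patients, config$n_controls, config$n_pharmaco)),
    allele_count = c(allele, rep(NA_integer_, config$n_controls),
                     rep(NA_integer_, config$n_pharmaco)),
    gender = c(gender, stats::rbinom(config$n_controls, 1L, 0.5),
               rep(1L, config$n_pharmaco)),
    dose = c(dose, rep(0, config$n_controls), rep(0, config$n_pharmaco)),
    stringsAsFactors = FALSE)

  rest <- data.frame(
    subject_id = c(pat_id, ctl_id),
    condition = rep("rest", length(pat_id) + length(ctl_id)),
    phase = rep(NA_character_, length(pat_id) + length(ctl_id)),
    order_index = rep(1L, length(pat_id) + length(ctl_id)),
    stringsAsFactors = FALSE)
  phr <- expand.grid(
    phase = c("pre", "post"),
    condition = c("ketamine", "midazolam", "placebo"),
    subject_id = phr_id,
    stringsAsFactors = FALSE)[, c("subject_id", "condition", "phase")]
  phr$order_index <- rep(1:6, times = config$n_pharmaco)
  sessions <- rbind(rest, phr)
  sessions$session <- ifelse(sessions$condition == "rest", "rest",
                             paste(sessions$condition, sessions$phase,
                                   sep = "_"))
  rownames(sessions) <- NULL
  list(cohort = cohort, sessions = sessions)
}

# Build the generating correlation matrix for one condition.
generating_correlation <- function(config, delta) {
  R <- length(config$region_labels)
  C <- matrix(config$base_cor, R, R)
  diag(C) <- 1
  sig <- match(config$signal_regions, config$region_labels)
  if (delta != 0 && length(sig) >= 2L) {
    W <- tcrossprod(config$signal_weights)
    C[sig, sig] <- C[sig, sig] + delta * W
    diag(C) <- 1
    C <- nearest_correlation(C)
  }
  dimnames(C) <- list(config$region_labels, config$region_labels)
  C
}

#' Simulate ROI time series for every subject and session
#'
#' Each subject/session matrix is drawn from a zero-mean multivariate
#' normal whose correlation matrix is the base matrix plus the planted
#' perturbation for that subject's allele count (patients) or the
#' session's condition/phase (pharmaco post sessions), projected to the
#' nearest valid correlation matrix. Deterministic given the config seed.
#'
#' @param cohort,sessions as returned by [simulate_cohort()].
#' @param config a [sim_config()].
#' @return An object of class \code{roi_ts_set}: list with
#'   \code{region_labels}, \code{series} (named list of T x R matrices,
#'   keyed "subject.session"), and \code{index} (data.frame subject_id,
#'   session, key).
#' @export
simulate_timeseries <- function(cohort, sessions, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  labels <- config$region_labels
  R <- length(labels)
  Tn <- config$n_timepoints

  # condition -> cholesky factor cache
  chol_cache <- new.env(parent = emptyenv())
  get_chol <- function(delta) {
    key <- format(delta, digits = 17)
    if (!exists(key, envir = chol_cache)) {
      assign(key, chol(generating_correlation(config, delta)),
             envir = chol_cache)
    }
    get(key, envir = chol_cache)
  }

  ord <- order(sessions$subject_id, sessions$session)
  sessions <- sessions[ord, , drop = FALSE]
  allele <- cohort$allele_count[match(sessions$subject_id,
                                      cohort$subject_id)]
  group <- cohort$group[match(sessions$subject_id, cohort$subject_id)]

  series <- vector("list", nrow(sessions))
  keys <- paste(sessions$subject_id, sessions$session, sep = ".")
  for (s in seq_len(nrow(sessions))) {
    delta <- 0
    if (group[s] == "patient" && !is.na(allele[s])) {
      delta <- allele[s] * config$allele_effect
    } else if (group[s] == "pharmaco" &&
               identical(sessions$phase[s], "post")) {
      if (sessions$condition[s] == "ketamine") delta <- config$ket_effect
      if (sessions$condition[s] == "midazolam") delta <- config$mdz_effect
    }
    z <- matrix(stats::rnorm(Tn * R), Tn, R)
    m <- (z %*% get_chol(delta)) * config$noise_sd
    colnames(m) <- labels
    series[[s]] <- m
  }
  names(series) <- keys
  structure(list(
    region_labels = labels,
    series = series,
    index = data.frame(subject_id = sessions$subject_id,
                       session = sessions$session,
                       key = keys, stringsAsFactors = FALSE)),
    class = "roi_ts_set")
}

#' Simulate Bern-scale symptom subcategory sums for patients
#'
#' The qualitative-language sum is generated from the latent score
#' \code{intercept - allele_slope * allele_count + edge_slope *
#' edge_connectivity + noise}, then discretized by rounding and clipping
#' to the subcategory's item-count range (items are bipolar -1/0/+1
#' ratings). The remaining eight subcategories (quantitative/subjective
#' language, three affective, three motor) are generated independently of
#' genotype. Deterministic given the config seed.
#'
#' @param cohort cohort table; only rows with group "patient" are scored.
#' @param edge_connectivity named numeric vector (per patient) of the
#'   connectivity value coupled into the language score; default all 0.
#' @param config a [sim_config()].
#' @return data.frame with subject_id and nine subcategory sum columns;
#'   attribute \code{latent_language_qualitative} holds the
#'   pre-discretization latent score.
#' @export
simulate_symptoms <- function(cohort, edge_connectivity = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  pat <- cohort[cohort$group == "patient", , drop = FALSE]
  n <- nrow(pat)
  if (n == 0L) stop("cohort contains no patients")
  if (is.null(edge_connectivity)) {
    edge_connectivity <- stats::setNames(rep(0, n), pat$subject_id)
  }
  edge <- edge_connectivity[pat$subject_id]
  if (any(is.na(edge))) stop("edge_connectivity missing for some patients")

  set.seed(config$seed + 2L)
  k <- config$symptom_items
  clipsum <- function(x) pmin(pmax(round(x), -k), k)

  latent <- config$symptom_intercept -
    config$symptom_allele_slope * pat$allele_count +
    config$symptom_edge_slope * edge +
    stats::rnorm(n, 0, config$symptom_noise_sd)

  other <- c("language_quantitative", "language_subjective",
             "affective_inhibition", "affective_disinhibition",
             "affective_lability", "motor_hypokinetic",
             "motor_hyperkinetic", "motor_parakinetic")
  out <- data.frame(subject_id = pat$subject_id, stringsAsFactors = FALSE)
  out$language_qualitative <- as.integer(clipsum(latent))
  for (col in other) {
    out[[col]] <- as.integer(clipsum(stats::rnorm(n, 0, 2)))
  }
  out <- out[, c("subject_id", "language_quantitative",
                 "language_qualitative", "language_subjective",
                 "affective_inhibition", "affective_disinhibition",
                 "affective_lability", "motor_hypokinetic",
                 "motor_hyperkinetic", "motor_parakinetic")]
  attr(out, "latent_language_qualitative") <-
    stats::setNames(latent, pat$subject_id)
  out
}

#' Symptom subcategory columns grouped by domain
#'
#' @return Named list mapping domain to its subcategory column names.
#' @export
symptom_domains <- function() {
  list(
    language = c("language_quantitative", "language_qualitative",
                 "language_subjective"),
    affective = c("affective_inhibition", "affective_disinhibition",
                  "affective_lability"),
    motor = c("motor_hypokinetic", "motor_hyperkinetic",
              "motor_parakinetic"))
}
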