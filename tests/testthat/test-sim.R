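small_cfg <- function(...) {
  tab <- default_region_table()
  sim_config(seed = 11, n_patients = 24, n_controls = 8, n_pharmaco = 4,
             n_timepoints = 40, region_labels = tab$name[1:8], ...)
}

test_that("the full synthetic dataset is reproducible bit-exactly", {
  cfg <- small_cfg(signal_regions = default_region_table()$name[1:3],
                   allele_effect = 0.2, ket_effect = 0.2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ts1 <- simulate_timeseries(a$cohort, a$sessions, cfg)
  ts2 <- simulate_timeseries(b$cohort, b$sessions, cfg)
  expect_identical(ts1$series, ts2$series)
  sy1 <- simulate_symptoms(a$cohort, NULL, cfg)
  sy2 <- simulate_symptoms(b$cohort, NULL, cfg)
  expect_identical(sy1, sy2)
})

test_that("cohort structure follows the study design", {
  cfg <- small_cfg()
  cs <- simulate_cohort(cfg)
  co <- cs$cohort
  expect_false(anyDuplicated(co$subject_id) > 0)
  expect_true(all(co$allele_count[co$group == "patient"] %in% 0:2))
  expect_true(all(is.na(co$allele_count[co$group != "patient"])))
  expect_true(all(co$dose >= 0))
  expect_true(all(co$dose[co$group != "patient"] == 0))
  # pharmaco subjects: 6 sessions (3 conditions x pre/post); others 1
  ses <- cs$sessions
  tab <- table(ses$subject_id)
  phr <- co$subject_id[co$group == "pharmaco"]
  expect_true(all(tab[phr] == 6))
  expect_true(all(tab[setdiff(names(tab), phr)] == 1))
  expect_setequal(unique(ses$session[ses$subject_id %in% phr]),
                  c("ketamine_pre", "ketamine_post", "midazolam_pre",
                    "midazolam_post", "placebo_pre", "placebo_post"))
})

test_that("HWE genotype sampling lands inside the exact multinomial envelope", {
  cfg <- sim_config(seed = 1, n_patients = 146, allele_freq = 0.277,
                    n_controls = 0, n_pharmaco = 0,
                    region_labels = default_region_table()$name[1:5])
  co <- simulate_cohort(cfg)$cohort
  counts <- table(factor(co$allele_count, levels = 0:2))
  p <- 0.277
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  # per-genotype binomial 99% envelope (exact quantiles)
  for (gi in 1:3) {
    lo <- qbinom(0.005, 146, probs[gi])
    hi <- qbinom(0.995, 146, probs[gi])
    expect_gte(counts[gi], lo)
    expect_lte(counts[gi], hi)
  }
})

test_that("allele_freq at the boundary gives monomorphic cohorts", {
  cfg <- small_cfg(allele_freq = 0)
  co <- simulate_cohort(cfg)$cohort
  expect_true(all(co$allele_count[co$group == "patient"] == 0))
  expect_error(sim_config(allele_freq = 1.2), "allele_freq")
  expect_error(sim_config(allele_freq = -0.1), "allele_freq")
})

test_that("correlation projection returns valid correlation matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    R <- 12
    m <- matrix(0.1, R, R); diag(m) <- 1
    idx <- sample(R, 6)
    m[idx, idx] <- m[idx, idx] + 0.5
    diag(m) <- 1
    c2 <- nearest_correlation(m)
    expect_equal(c2, t(c2))
    expect_equal(unname(diag(c2)), rep(1, R))
    expect_true(min(eigen(c2, symmetric = TRUE,
                          only.values = TRUE)$values) >= -1e-8)
  }
})

test_that("null generator shows no genotype-dependent connectivity as T grows", {
  tab <- default_region_table()
  cfg <- sim_config(seed = 21, n_patients = 20, n_controls = 0,
                    n_pharmaco = 0, n_timepoints = 2000,
                    region_labels = tab$name[1:6])
  cohort <- data.frame(
    subject_id = sprintf("P%03d", 1:20),
    group = "patient",
    allele_count = rep(c(0L, 2L), each = 10),
    gender = 0L, dose = 0, stringsAsFactors = FALSE)
  sessions <- data.frame(subject_id = cohort$subject_id,
                         condition = "rest", phase = NA_character_,
                         order_index = 1L, session = "rest",
                         stringsAsFactors = FALSE)
  ts <- simulate_timeseries(cohort, sessions, cfg)
  Y <- stack_group(ts, cohort)
  d <- colMeans(Y[cohort$allele_count == 2, ]) -
    colMeans(Y[cohort$allele_count == 0, ])
  expect_lt(max(abs(d)), 0.05)
})

test_that("planted allele effect concentrates on signal-set edges", {
  tab <- default_region_table()
  labs <- tab$name[1:8]
  cfg <- sim_config(seed = 22, n_patients = 20, n_controls = 0,
                    n_pharmaco = 0, n_timepoints = 2000,
                    region_labels = labs, signal_regions = labs[1:4],
                    allele_effect = 0.3)
  cohort <- data.frame(
    subject_id = sprintf("P%03d", 1:20), group = "patient",
    allele_count = rep(c(0L, 2L), each = 10),
    gender = 0L, dose = 0, stringsAsFactors = FALSE)
  sessions <- data.frame(subject_id = cohort$subject_id,
                         condition = "rest", phase = NA_character_,
                         order_index = 1L, session = "rest",
                         stringsAsFactors = FALSE)
  ts <- simulate_timeseries(cohort, sessions, cfg)
  Y <- stack_group(ts, cohort)
  d <- colMeans(Y[cohort$allele_count == 2, ]) -
    colMeans(Y[cohort$allele_count == 0, ])
  idx <- lower_edge_index(length(labs))
  in_sig <- idx$i <= 4 & idx$j <= 4
  expect_gt(mean(d[in_sig]), 0)
  expect_gt(mean(d[in_sig]), 2 * abs(mean(d[!in_sig])))
})

test_that("symptom generator reduces to the exact latent model without noise", {
  cfg <- small_cfg(symptom_intercept = 2, symptom_allele_slope = 1,
                   symptom_edge_slope = 0, symptom_noise_sd = 0)
  cs <- simulate_cohort(cfg)
  sy <- simulate_symptoms(cs$cohort, NULL, cfg)
  pat <- cs$cohort[cs$cohort$group == "patient", ]
  latent <- attr(sy, "latent_language_qualitative")
  expect_equal(unname(latent[pat$subject_id]), 2 - pat$allele_count)
  expect_equal(sy$language_qualitative,
               as.integer(pmin(pmax(round(2 - pat$allele_count), -7), 7)))
})

test_that("symptom sums respect the bipolar item range", {
  cfg <- small_cfg(symptom_intercept = 50, symptom_noise_sd = 30)
  cs <- simulate_cohort(cfg)
  sy <- simulate_symptoms(cs$cohort, NULL, cfg)
  for (col in unlist(symptom_domains())) {
    expect_true(all(abs(sy[[col]]) <= cfg$symptom_items))
  }
})

test_that("planted genotype-symptom coupling is recovered as a negative partial correlation", {
  neg <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    cfg <- sim_config(seed = 1000 + i, n_patients = 146, n_controls = 0,
                      n_pharmaco = 0,
                      region_labels = default_region_table()$name[1:5],
                      symptom_allele_slope = 0.5, symptom_noise_sd = 1)
    co <- simulate_cohort(cfg)$cohort
    sy <- simulate_symptoms(co, NULL, cfg)
    pat <- co[co$group == "patient", ]
    pc <- partial_corr(pat$allele_count, sy$language_qualitative,
                       cbind(pat$gender, pat$dose))
    if (pc$r < 0) neg <- neg + 1
  }
  expect_gte(neg / reps, 0.95)
})

test_that("uncoupled symptoms show null-rate association with genotype", {
  sig <- 0
  reps <- 100
  for (i in seq_len(reps)) {
    cfg <- sim_config(seed = 3000 + i, n_patients = 100, n_controls = 0,
                      n_pharmaco = 0,
                      region_labels = default_region_table()$name[1:5])
    co <- simulate_cohort(cfg)$cohort
    sy <- simulate_symptoms(co, NULL, cfg)
    pat <- co[co$group == "patient", ]
    pc <- partial_corr(pat$allele_count, sy$language_qualitative,
                       cbind(pat$gender, pat$dose))
    if (pc$p < 0.05) sig <- sig + 1
  }
  expect_lte(sig / reps, 0.12)
})
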