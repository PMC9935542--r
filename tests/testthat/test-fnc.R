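test_that("every named a-priori region set resolves against the label table", {
  nets <- default_networks()
  tab <- default_region_table()
  for (nm in names(nets)) {
    expect_true(all(nets[[nm]]$regions %in% tab$name), label = nm)
  }
  expect_equal(length(nets$spt$regions), 8)   # 4 structures, bilateral
  expect_setequal(
    nets$spt$regions,
    c("Caudate l", "Caudate r", "Putamen l", "Putamen r", "Pallidum l",
      "Pallidum r", "Thalamus l", "Thalamus r"))
  expect_true(all(c("Heschl's Gyrus l", "Planum Temporale r",
                    "Posterior Superior Temporal Gyrus l",
                    "Precentral Gyrus r", "Postcentral Gyrus l",
                    "Insular Cortex r") %in% nets$asm$regions))
})

test_that("a degenerate single-pair network test reduces to the edge GLM", {
  labels <- paste0("r", 1:6)
  Y <- gauss_stack(24, labels, seed = 111)
  X <- allele_design(24, seed = 112)
  res <- fnc_test(Y, X, "r2", "r5")
  em <- fit_edge_glm(Y, X)
  expect_equal(res$effect, em$effect["r2", "r5"], tolerance = 1e-12)
  expect_equal(res$statistic, em$t["r2", "r5"], tolerance = 1e-12)
  expect_equal(res$p, em$p["r2", "r5"], tolerance = 1e-12)
})

test_that("the set-level effect equals the mean of per-edge effects", {
  labels <- paste0("r", 1:8)
  Y <- gauss_stack(30, labels, seed = 113)
  X <- allele_design(30, seed = 114)
  res <- fnc_test(Y, X, labels[1:3], labels[4:7])
  em <- fit_edge_glm(Y, X)
  per_edge <- outer(labels[1:3], labels[4:7],
                    Vectorize(function(a, b) em$effect[a, b]))
  expect_equal(res$effect, mean(per_edge), tolerance = 1e-10)
})

test_that("set-level validation catches overlap and empty sets", {
  labels <- paste0("r", 1:6)
  Y <- gauss_stack(20, labels, seed = 115)
  X <- allele_design(20, seed = 116)
  expect_error(fnc_test(Y, X, c("r1", "r2"), c("r2", "r3")), "disjoint")
  expect_error(fnc_test(Y, X, "r1"), ">= 2 regions")
  expect_error(fnc_test(Y, X, c("r1", "zz"), c("r3")), "unknown region")
})

test_that("planted set-to-set hyper-connectivity is detected with the right sign", {
  nets <- default_networks()
  labs <- c(nets$spt$regions, nets$asm$regions)
  hits <- 0
  n_seeds <- 30
  for (i in seq_len(n_seeds)) {
    Y <- gauss_stack(146, labs, seed = 7000 + i, sd = 0.12)
    X <- allele_design(146, seed = 8000 + i)
    cols <- unlist(lapply(match(nets$spt$regions, labs), function(a) {
      vapply(match(nets$asm$regions, labs), function(b) {
        hi <- max(a, b); lo <- min(a, b)
        (hi - 1) * (hi - 2) / 2 + lo
      }, numeric(1))
    }))
    Y[, cols] <- Y[, cols] + 0.08 * X[, "allele"]
    res <- fnc_test(Y, X, nets$spt, nets$asm)
    if (res$effect > 0 && res$p < 0.05) hits <- hits + 1
    expect_true(all(paste(res$contributing_edges$region_a,
                          res$contributing_edges$region_b) %in%
                      c(outer(nets$spt$regions, nets$asm$regions, paste),
                        outer(nets$asm$regions, nets$spt$regions, paste))))
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("null data give nominal set-level false-positive rates", {
  nets <- default_networks()
  labs <- c(nets$spt$regions, nets$asm$regions)
  fp <- 0
  n_runs <- 200
  for (i in seq_len(n_runs)) {
    Y <- gauss_stack(60, labs, seed = 9000 + i, sd = 0.12)
    X <- allele_design(60, seed = 10000 + i)
    if (fnc_test(Y, X, nets$spt, nets$asm)$p < 0.05) fp <- fp + 1
  }
  se <- sqrt(0.05 * 0.95 / n_runs)
  expect_lte(fp / n_runs, 0.05 + 3 * se)
  expect_gte(fp / n_runs, 0.05 - 3 * se)
})

test_that("hierarchical clustering recovers planted blocks exactly", {
  labels <- paste0("r", sprintf("%02d", 1:12))
  block <- rep(1:3, each = 4)
  M <- 0.05 + 0.75 * outer(block, block, "==")
  set.seed(117)
  noise <- matrix(rnorm(144, sd = 0.02), 12, 12)
  M <- M + (noise + t(noise)) / 2
  diag(M) <- 0
  dimnames(M) <- list(labels, labels)
  nets <- cluster_networks(M, k = 3)
  got <- lapply(nets, function(n) sort(n$regions))
  want <- lapply(1:3, function(b) sort(labels[block == b]))
  expect_setequal(got, want)
})

test_that("clustering honors the degenerate and invariance contracts", {
  M <- rand_sym(8, 118)
  # k = R -> singletons
  nets <- cluster_networks(M, k = 8)
  expect_equal(sort(vapply(nets, function(n) n$regions, character(1))),
               sort(rownames(M)))
  expect_error(cluster_networks(M, k = 9), "exceeds")
  expect_error(cluster_networks(M, k = 1), "at least 2")
  # invariance to region input order
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  Mp <- M[perm, perm]
  n1 <- cluster_networks(M, k = 3)
  n2 <- cluster_networks(Mp, k = 3)
  expect_equal(lapply(n1, function(n) n$regions),
               lapply(n2, function(n) n$regions))
  # duplicated region rows always co-cluster
  Md <- M
  Md["r2", ] <- Md["r1", ]
  Md[, "r2"] <- Md[, "r1"]
  Md["r1", "r2"] <- Md["r2", "r1"] <- Md["r1", "r2"]
  diag(Md) <- 0
  for (k in c(2, 4, 6)) {
    nets_k <- cluster_networks(Md, k = k)
    cl_of <- function(r) which(vapply(nets_k, function(n) {
      r %in% n$regions
    }, logical(1)))
    expect_equal(cl_of("r1"), cl_of("r2"))
  }
})

test_that("all-pairs network testing enumerates k(k+1)/2 tests with FDR", {
  labels <- paste0("r", sprintf("%02d", 1:12))
  Y <- gauss_stack(30, labels, seed = 119)
  X <- allele_design(30, seed = 120)
  nets <- lapply(1:4, function(g) {
    network_def(paste0("n", g), labels[(3 * g - 2):(3 * g)],
                region_table = NULL)
  })
  res <- fnc_all_pairs(Y, X, nets)
  expect_equal(nrow(res), 10)  # 4 within + 6 between
  expect_equal(sum(res$type == "within"), 4)
  expect_equal(res$p_fdr, p.adjust(res$p, "BH"))
})

test_that("planted auditory-visual hypo-connectivity is flagged negative and significant", {
  nets <- default_networks()
  stg <- nets$stg
  tov <- nets$temporo_occipital
  labs <- c(stg$regions, tov$regions, "Frontal Pole l", "Frontal Pole r",
            "Precuneous Cortex l", "Precuneous Cortex r")
  extra <- network_def("frontal-parietal",
                       c("Frontal Pole l", "Frontal Pole r",
                         "Precuneous Cortex l", "Precuneous Cortex r"))
  hits <- 0
  n_seeds <- 30
  for (i in seq_len(n_seeds)) {
    Y <- gauss_stack(146, labs, seed = 11000 + i, sd = 0.12)
    X <- allele_design(146, seed = 12000 + i)
    cols <- unlist(lapply(match(stg$regions, labs), function(a) {
      vapply(match(tov$regions, labs), function(b) {
        hi <- max(a, b); lo <- min(a, b)
        (hi - 1) * (hi - 2) / 2 + lo
      }, numeric(1))
    }))
    Y[, cols] <- Y[, cols] - 0.06 * X[, "allele"]
    res <- fnc_all_pairs(Y, X, list(stg, tov, extra))
    row <- which(res$network_a == "superior-temporal" &
                   res$network_b == "temporo-occipital")
    if (res$effect[row] < 0 && res$significant[row]) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("seed profiles detect a planted edge and stay calibrated under the null", {
  labels <- default_region_table()$name[1:20]
  cuneus <- "Insular Cortex l"  # any seed region in the subset
  target <- labels[15]
  hits <- 0
  for (i in 1:30) {
    Y <- gauss_stack(146, labels, seed = 13000 + i, sd = 0.12)
    X <- allele_design(146, seed = 14000 + i)
    col <- edge_col_of(Y, cuneus, target)
    Y[, col] <- Y[, col] + 0.1 * X[, "allele"]
    sp <- seed_profile(Y, X, cuneus)
    row <- which(sp$target == target)
    if (sp$significant[row] && sp$effect[row] > 0) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
  # null calibration: expected false positives bounded by q
  fp <- 0
  n_runs <- 100
  for (i in 1:n_runs) {
    Y <- gauss_stack(60, labels, seed = 15000 + i, sd = 0.12)
    X <- allele_design(60, seed = 16000 + i)
    fp <- fp + sum(seed_profile(Y, X, cuneus)$significant)
  }
  expect_lte(fp / (n_runs * 19), 0.05)
  expect_error(seed_profile(gauss_stack(20, labels, 1), allele_design(20, 2),
                            "No Such Region"), "unknown seed")
})
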