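toy_atlas <- function() {
  tab <- data.frame(label = c(3L, 9L), name = c("regA", "regB"),
                    stringsAsFactors = FALSE)
  grid <- array(0L, c(4, 4, 4))
  grid[2, 2, 2] <- 3L
  grid[3, 3, 3] <- 9L
  affine <- rbind(cbind(diag(2, 3), c(-3, -3, -3)), c(0, 0, 0, 1))
  structure(list(label_grid = grid, affine = affine,
                 label_names = setNames(tab$name, tab$label),
                 region_table = tab),
            class = "atlas_volume")
}

test_that("samples inside a labeled voxel are assigned by containment", {
  atlas <- toy_atlas()
  # voxel (2,2,2) 1-based -> 0-based (1,1,1) -> mm (2*1-3, ...) = (-1,-1,-1)
  s <- data.frame(sample_id = "s1", x = -1, y = -1, z = -1)
  asg <- assign_samples(s, atlas, tolerance_mm = 2)
  expect_equal(asg$region, "regA")
  expect_equal(asg$distance_mm, 0)
})

test_that("far-away samples stay unassigned; near misses snap within tolerance", {
  atlas <- toy_atlas()
  far <- data.frame(sample_id = "s_far", x = 50, y = 50, z = 50)
  expect_true(is.na(assign_samples(far, atlas, 2)$region))
  # 1.5 mm from the regB voxel center (1,1,1) mm
  near <- data.frame(sample_id = "s_near", x = 2.5, y = 1, z = 1)
  hit <- assign_samples(near, atlas, 2)
  # brute-force nearest labeled voxel oracle
  idx <- which(atlas$label_grid > 0, arr.ind = TRUE)
  mm <- (idx - 1) * 2 + matrix(rep(c(-3, -3, -3), nrow(idx)),
                               ncol = 3, byrow = TRUE)
  d <- sqrt(rowSums((mm - matrix(c(2.5, 1, 1), nrow(idx), 3,
                                 byrow = TRUE))^2))
  best <- which.min(d)
  expect_equal(hit$label, atlas$label_grid[idx[best, , drop = FALSE]])
  expect_equal(hit$region, "regB")
  expect_equal(hit$distance_mm, min(d), tolerance = 1e-12)
  expect_lte(hit$distance_mm, 2)
})

test_that("a singular affine is rejected", {
  atlas <- toy_atlas()
  atlas$affine[1, 1] <- 0
  atlas$affine[1, ] <- 0
  s <- data.frame(sample_id = "s1", x = 0, y = 0, z = 0)
  expect_error(assign_samples(s, atlas), "not invertible")
})

test_that("two-point regional z-scores match the closed form", {
  tab <- data.frame(label = 1:2, name = c("regA", "regB"))
  samples <- data.frame(sample_id = c("a", "b"), donor_id = "d1",
                        x = 0, y = 0, z = 0, g1 = c(1, -1))
  assignment <- data.frame(sample_id = c("a", "b"),
                           region = c("regA", "regB"))
  expect_error(build_profiles(samples, assignment, "g1",
                              region_table = tab),
               "fewer than 3 regions")
  # add a third region to satisfy the support precondition
  tab3 <- data.frame(label = 1:3, name = c("regA", "regB", "regC"))
  samples3 <- data.frame(sample_id = c("a", "b", "c"), donor_id = "d1",
                         x = 0, y = 0, z = 0, g1 = c(1, -1, 0))
  assignment3 <- data.frame(sample_id = c("a", "b", "c"),
                            region = c("regA", "regB", "regC"))
  prof <- build_profiles(samples3, assignment3, "g1", region_table = tab3)
  expect_equal(prof$z_g1, (c(1, -1, 0) - 0) / sd(c(1, -1, 0)),
               tolerance = 1e-12)
  expect_equal(prof$rank, c(1L, 3L, 2L))
  # invariant: z has mean 0 and sd 1 across supported regions
  expect_equal(mean(prof$z_g1), 0, tolerance = 1e-9)
  expect_equal(sd(prof$z_g1), 1, tolerance = 1e-9)
})

test_that("identical marker genes give a combined score equal to one gene's z", {
  tab <- data.frame(label = 1:4, name = paste0("reg", 1:4))
  set.seed(101)
  samples <- data.frame(sample_id = sprintf("s%02d", 1:12),
                        donor_id = rep(c("d1", "d2"), each = 6),
                        x = 0, y = 0, z = 0)
  v <- rnorm(12)
  samples$g1 <- v; samples$g2 <- v; samples$g3 <- v
  assignment <- data.frame(sample_id = samples$sample_id,
                           region = rep(paste0("reg", 1:4), 3))
  prof <- build_profiles(samples, assignment, c("g1", "g2", "g3"),
                         region_table = tab)
  expect_equal(prof$combined_score, prof$z_g1, tolerance = 1e-12)
})

test_that("the donor-first aggregation matches an independent recomputation", {
  # 3 donors x 4 regions x 2 genes
  tab <- data.frame(label = 1:4, name = paste0("reg", 1:4))
  set.seed(102)
  n_per <- c(d1 = 8, d2 = 12, d3 = 6)
  samples <- do.call(rbind, lapply(names(n_per), function(d) {
    data.frame(sample_id = paste0(d, "_", seq_len(n_per[[d]])),
               donor_id = d, x = 0, y = 0, z = 0,
               gA = rnorm(n_per[[d]], mean = 10, sd = 2),
               gB = rnorm(n_per[[d]], mean = 5, sd = 1))
  }))
  assignment <- data.frame(
    sample_id = samples$sample_id,
    region = unlist(lapply(n_per, function(k) {
      rep_len(paste0("reg", 1:4), k)
    })))
  prof <- build_profiles(samples, assignment, c("gA", "gB"),
                         region_table = tab)
  # independent spreadsheet-style recomputation with explicit loops
  dat <- merge(samples, assignment, by = "sample_id")
  for (g in c("gA", "gB")) {
    zmat <- matrix(NA_real_, 4, 3,
                   dimnames = list(paste0("reg", 1:4), names(n_per)))
    for (d in names(n_per)) {
      sub <- dat[dat$donor_id == d, ]
      z <- (sub[[g]] - mean(sub[[g]])) / sd(sub[[g]])
      for (rg in paste0("reg", 1:4)) {
        zmat[rg, d] <- mean(z[sub$region == rg])
      }
    }
    reg_mean <- rowMeans(zmat)
    reg_z <- (reg_mean - mean(reg_mean)) / sd(reg_mean)
    expect_equal(prof[[paste0("z_", g)]], unname(reg_z),
                 tolerance = 1e-12)
  }
  expect_equal(prof$combined_score, (prof$z_gA + prof$z_gB) / 2,
               tolerance = 1e-12)
  expect_setequal(prof$rank, 1:4)
})

test_that("ranking is invariant to a donor's affine intensity rescaling", {
  tab <- default_region_table()[1:12, ]
  atlas <- make_synthetic_atlas(tab)
  samples <- simulate_expression_samples(atlas, n_donors = 3,
                                         samples_per_donor = 60, seed = 9)
  assignment <- assign_samples(samples, atlas)
  genes <- c("GRIN1", "PV", "SLC17A7")
  p1 <- build_profiles(samples, assignment, genes, region_table = tab)
  rescaled <- samples
  d1 <- rescaled$donor_id == "donor01"
  for (g in genes) rescaled[[g]][d1] <- 100 + 3 * rescaled[[g]][d1]
  p2 <- build_profiles(rescaled, assignment, genes, region_table = tab)
  expect_equal(p1$rank, p2$rank)
  expect_equal(p1$combined_score, p2$combined_score, tolerance = 1e-9)
})

test_that("profiles are invariant to sample order and support the GRIN2A swap", {
  tab <- default_region_table()[1:10, ]
  atlas <- make_synthetic_atlas(tab)
  samples <- simulate_expression_samples(
    atlas, genes = c("GRIN2A", "PV", "SLC17A7"), n_donors = 3,
    samples_per_donor = 50, seed = 10)
  assignment <- assign_samples(samples, atlas)
  genes <- c("GRIN2A", "PV", "SLC17A7")
  p1 <- build_profiles(samples, assignment, genes, region_table = tab)
  set.seed(11)
  perm <- sample(nrow(samples))
  p2 <- build_profiles(samples[perm, ], assignment, genes,
                       region_table = tab)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(c("z_GRIN2A", "z_PV", "z_SLC17A7") %in% names(p1)))
})

test_that("unsupported regions are flagged and ranked last", {
  tab <- default_region_table()[1:6, ]
  samples <- data.frame(sample_id = sprintf("s%d", 1:8),
                        donor_id = rep(c("d1", "d2"), 4),
                        x = 0, y = 0, z = 0, g1 = rnorm(8))
  assignment <- data.frame(sample_id = samples$sample_id,
                           region = rep(tab$name[1:4], 2))
  prof <- build_profiles(samples, assignment, "g1", region_table = tab)
  expect_equal(sum(prof$supported), 4)
  expect_equal(sort(prof$rank[!prof$supported]), c(5L, 6L))
  expect_true(all(is.na(prof$combined_score[!prof$supported])))
})

test_that("the synthetic generator's planted regional scores drive the ranking", {
  tab <- default_region_table()[1:15, ]
  atlas <- make_synthetic_atlas(tab)
  scores <- setNames(seq(2, -2, length.out = 15), tab$name)
  samples <- simulate_expression_samples(atlas, n_donors = 6,
                                         samples_per_donor = 120,
                                         region_scores = scores, seed = 12)
  assignment <- assign_samples(samples, atlas)
  prof <- build_profiles(samples, assignment, c("GRIN1", "PV", "SLC17A7"),
                         region_table = tab)
  recovered <- prof$rank[match(names(sort(-scores)), prof$region)]
  expect_gt(cor(recovered, seq_len(15), method = "spearman"), 0.9)
})

test_that("atlas volumes survive a NIfTI round trip", {
  tab <- default_region_table()[1:8, ]
  atlas <- make_synthetic_atlas(tab)
  nii <- tempfile(fileext = ".nii.gz")
  lab <- tempfile(fileext = ".tsv")
  write_atlas(atlas, nii, lab)
  back <- read_atlas(nii, lab)
  expect_equal(back$label_grid, atlas$label_grid, ignore_attr = TRUE)
  expect_equal(back$affine, atlas$affine, tolerance = 1e-5)
  expect_equal(back$label_names, atlas$label_names)
  # assignment must agree between original and reloaded atlas
  samples <- simulate_expression_samples(atlas, n_donors = 2,
                                         samples_per_donor = 40, seed = 13)
  a1 <- assign_samples(samples, atlas)
  a2 <- assign_samples(samples, back)
  expect_equal(a1$label, a2$label)
})
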