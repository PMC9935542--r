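#' Construct a synthetic labeled atlas volume
#'
#' Builds a small 3-D label grid emulating a parcellation volume: a
#' one-voxel background shell surrounds a foreground block whose voxels
#' are assigned to the regions of \code{region_table} in contiguous runs,
#' so every label appears. The affine maps 0-based voxel indices to mm
#' coordinates (NIfTI convention), centered on the grid.
#'
#' @param region_table region table (label, name).
#' @param dim grid dimensions (must give enough foreground voxels).
#' @param voxel_mm isotropic voxel size in mm.
#' @return Object of class \code{atlas_volume}: list with
#'   \code{label_grid} (integer array), \code{affine} (4x4),
#'   \code{label_names} (named character, names = label integers), and
#'   \code{region_table}.
#' @export
make_synthetic_atlas <- function(region_table = default_region_table(),
                                 dim = c(10L, 10L, 12L), voxel_mm = 4) {
  R <- nrow(region_table)
  fg_dim <- dim - 2L
  n_fg <- prod(fg_dim)
  if (n_fg < R) stop("grid too small for ", R, " regions")
  grid <- array(0L, dim)
  fg_labels <- region_table$label[ceiling(seq_len(n_fg) * R / n_fg)]
  grid[2:(dim[1] - 1L), 2:(dim[2] - 1L), 2:(dim[3] - 1L)] <-
    array(fg_labels, fg_dim)
  affine <- rbind(cbind(diag(voxel_mm, 3L),
                        -voxel_mm * (dim - 1) / 2),
                  c(0, 0, 0, 1))
  structure(list(
    label_grid = grid,
    affine = affine,
    label_names = stats::setNames(region_table$name,
                                  as.character(region_table$label)),
    region_table = region_table),
    class = "atlas_volume")
}

#' Read an atlas from a NIfTI volume and a label table
#'
#' @param nii_path path to a .nii/.nii.gz label volume.
#' @param label_table data.frame with columns \code{label} and
#'   \code{name}, or a path to a TSV with those columns.
#' @return \code{atlas_volume}, see [make_synthetic_atlas()].
#' @export
read_atlas <- function(nii_path, label_table) {
  img <- RNifti::readNifti(nii_path)
  if (is.character(label_table)) {
    label_table <- utils::read.delim(label_table, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("label", "name") %in% names(label_table)))
  affine <- structure(RNifti::xform(img), class = NULL)
  grid <- array(as.integer(round(as.array(img))), dim(img))
  structure(list(
    label_grid = grid,
    affine = matrix(as.numeric(affine), 4L, 4L),
    label_names = stats::setNames(label_table$name,
                                  as.character(label_table$label)),
    region_table = label_table),
    class = "atlas_volume")
}

#' Write an atlas volume to NIfTI + TSV label table
#'
#' @param atlas \code{atlas_volume}.
#' @param nii_path,label_path output paths.
#' @return Invisibly, the paths.
#' @export
write_atlas <- function(atlas, nii_path, label_path) {
  img <- RNifti::asNifti(atlas$label_grid)
  img <- RNifti::`sform<-`(img, structure(atlas$affine, code = 2L))
  RNifti::writeNifti(img, nii_path)
  utils::write.table(
    data.frame(label = as.integer(names(atlas$label_names)),
               name = unname(atlas$label_names)),
    label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nii_path, label_path))
}

# mm coordinates of every labeled voxel (rows) with their labels.
labeled_voxel_mm <- function(atlas) {
  idx <- which(atlas$label_grid > 0L, arr.ind = TRUE)
  vox0 <- idx - 1  # 0-based
  mm <- cbind(vox0, 1) %*% t(atlas$affine)
  list(mm = mm[, 1:3, drop = FALSE],
       label = atlas$label_grid[idx])
}

#' Assign expression samples to atlas regions
#'
#' Each sample is assigned to the label of its containing voxel; samples
#' falling on background are assigned to the nearest labeled voxel within
#' \code{tolerance_mm} (Euclidean distance in mm), otherwise left
#' unassigned.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{x},
#'   \code{y}, \code{z} (mm coordinates).
#' @param atlas \code{atlas_volume}.
#' @param tolerance_mm nearest-voxel search radius (default 2).
#' @return data.frame with \code{sample_id}, \code{region} (region name,
#'   NA if unassigned), \code{label} (integer), \code{distance_mm} (0 for
#'   containment).
#' @export
assign_samples <- function(samples, atlas, tolerance_mm = 2) {
  if (abs(det(atlas$affine)) < 1e-12) stop("atlas affine is not invertible")
  inv <- solve(atlas$affine)
  dims <- dim(atlas$label_grid)
  xyz <- as.matrix(samples[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("sample coordinates must be finite")
  vox <- round(cbind(xyz, 1) %*% t(inv))[, 1:3, drop = FALSE] + 1  # 1-based
  label <- rep(NA_integer_, nrow(samples))
  dist <- rep(NA_real_, nrow(samples))
  inside <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
    vox[, 2] >= 1 & vox[, 2] <= dims[2] &
    vox[, 3] >= 1 & vox[, 3] <= dims[3]
  if (any(inside)) {
    lin <- vox[inside, 1] + dims[1] * (vox[inside, 2] - 1) +
      dims[1] * dims[2] * (vox[inside, 3] - 1)
    lab <- atlas$label_grid[lin]
    label[inside][lab > 0L] <- lab[lab > 0L]
    dist[inside][lab > 0L] <- 0
  }
  todo <- which(is.na(label))
  if (length(todo) > 0L) {
    lv <- labeled_voxel_mm(atlas)
    for (s in todo) {
      d2 <- (lv$mm[, 1] - xyz[s, 1])^2 + (lv$mm[, 2] - xyz[s, 2])^2 +
        (lv$mm[, 3] - xyz[s, 3])^2
      best <- which.min(d2)
      if (sqrt(d2[best]) <= tolerance_mm) {
        label[s] <- lv$label[best]
        dist[s] <- sqrt(d2[best])
      }
    }
  }
  data.frame(sample_id = samples$sample_id,
             region = unname(atlas$label_names[as.character(label)]),
             label = label,
             distance_mm = dist,
             stringsAsFactors = FALSE)
}

#' Simulate postmortem microarray expression samples
#'
#' Emulates a six-donor whole-brain microarray dataset with
#' region-structured marker-gene expression: each region carries a latent
#' marker score shared (with gene-specific wobble) by all marker genes;
#' each donor measures it on its own affine intensity scale (random
#' intercept and positive gain per gene), plus sampling noise. Sample
#' locations are uniformly drawn labeled voxels, jittered within the
#' voxel.
#'
#' @param atlas \code{atlas_volume}.
#' @param genes marker gene symbols.
#' @param n_donors number of donors.
#' @param samples_per_donor samples drawn per donor.
#' @param region_scores optional named numeric vector (region name ->
#'   latent score); default drawn N(0,1) from the seed.
#' @param gene_wobble_sd sd of the per-gene deviation from the shared
#'   regional score.
#' @param noise_sd per-sample measurement noise sd.
#' @param seed RNG seed.
#' @return data.frame: sample_id, donor_id, x, y, z, one column per gene.
#'   Attribute \code{region_scores} carries the generating latent scores.
#' @export
simulate_expression_samples <- function(atlas,
                                        genes = c("GRIN1", "PV", "SLC17A7"),
                                        n_donors = 6L,
                                        samples_per_donor = 150L,
                                        region_scores = NULL,
                                        gene_wobble_sd = 0.15,
                                        noise_sd = 0.4,
                                        seed = 1L) {
  set.seed(seed)
  regions <- unname(atlas$label_names)
  if (is.null(region_scores)) {
    region_scores <- stats::setNames(stats::rnorm(length(regions)), regions)
  }
  # per-region per-gene true profile: shared score + gene wobble
  true_profile <- sapply(genes, function(g) {
    region_scores + stats::rnorm(length(regions), 0, gene_wobble_sd)
  })
  rownames(true_profile) <- regions

  lv <- labeled_voxel_mm(atlas)
  vox_mm <- abs(atlas$affine[1, 1])
  out <- list()
  for (d in seq_len(n_donors)) {
    pick <- sample.int(nrow(lv$mm), samples_per_donor, replace = TRUE)
    jitter <- matrix(stats::runif(3L * samples_per_donor, -vox_mm / 2,
                                  vox_mm / 2), ncol = 3L)
    coords <- lv$mm[pick, , drop = FALSE] + jitter
    region <- unname(atlas$label_names[as.character(lv$label[pick])])
    df <- data.frame(
      sample_id = sprintf("D%02d_S%03d", d, seq_len(samples_per_donor)),
      donor_id = sprintf("donor%02d", d),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
    for (g in genes) {
      intercept <- stats::rnorm(1L, 7, 1.5)
      gain <- stats::rlnorm(1L, 0, 0.25)
      df[[g]] <- intercept + gain *
        (true_profile[region, g] +
           stats::rnorm(samples_per_donor, 0, noise_sd))
    }
    out[[d]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "region_scores") <- region_scores
  res
}

#' Donor-normalized regional marker-gene expression profiles
#'
#' Aggregation pipeline (donor-first, so donors with more samples cannot
#' dominate): per donor, z-score each gene across that donor's assigned
#' samples; average samples within region per donor; average the region
#' values across donors; z-score the resulting regional vector across
#' supported regions. The combined score is the mean z over the marker
#' genes, and regions are ranked in descending combined-score order
#' (ties broken by region label order). Regions with fewer than
#' \code{min_samples} samples are unsupported: they receive the last
#' ranks (in label order) and are flagged, and are excluded from curve
#' analyses by default.
#'
#' @param samples expression sample table (see
#'   [simulate_expression_samples()]).
#' @param assignment sample-to-region assignment from
#'   [assign_samples()].
#' @param genes marker gene columns to use (e.g. swap GRIN1 for GRIN2A).
#' @param min_samples minimum per-region sample support (default 1).
#' @param region_table regions to profile; default from the assignment's
#'   observed regions is not used — supply the atlas table so unsampled
#'   regions are reported as unsupported.
#' @return Object of classes \code{region_profile}/\code{data.frame}:
#'   columns \code{region}, \code{n_samples}, one z column per gene
#'   (\code{z_<gene>}), \code{combined_score}, \code{rank},
#'   \code{supported}.
#' @export
build_profiles <- function(samples, assignment, genes,
                           min_samples = 1L,
                           region_table = default_region_table()) {
  stopifnot(all(genes %in% names(samples)))
  df <- merge(samples, assignment[, c("sample_id", "region")],
              by = "sample_id", sort = FALSE)
  df <- df[!is.na(df$region), , drop = FALSE]
  regions <- region_table$name

  # per-donor z-scores across that donor's samples
  for (g in genes) {
    df[[paste0(".z_", g)]] <- stats::ave(df[[g]], df$donor_id,
                                         FUN = function(v) {
                                           (v - mean(v)) / stats::sd(v)
                                         })
  }
  # donor x region means, then cross-donor mean per region
  donor_region_mean <- function(zcol) {
    agg <- stats::aggregate(df[[zcol]],
                            by = list(region = df$region,
                                      donor = df$donor_id),
                            FUN = mean)
    tapply(agg$x, agg$region, mean)
  }
  support <- table(factor(df$region, levels = regions))
  supported <- as.integer(support) >= min_samples & as.integer(support) > 0L
  if (sum(supported) < 3L) {
    stop("fewer than 3 regions with sample support >= ", min_samples)
  }

  zmat <- matrix(NA_real_, length(regions), length(genes),
                 dimnames = list(regions, genes))
  for (g in genes) {
    m <- donor_region_mean(paste0(".z_", g))
    zmat[names(m), g] <- m
  }
  zmat[!supported, ] <- NA_real_
  # z-score each gene's regional vector across supported regions
  for (g in genes) {
    v <- zmat[supported, g]
    zmat[supported, g] <- (v - mean(v)) / stats::sd(v)
  }
  combined <- rowMeans(zmat)

  out <- data.frame(region = regions,
                    n_samples = as.integer(support),
                    stringsAsFactors = FALSE)
  for (g in genes) out[[paste0("z_", g)]] <- zmat[, g]
  out$combined_score <- combined
  out$supported <- supported
  # descending combined score; unsupported regions last; ties and the
  # unsupported block ordered by region label order
  key <- ifelse(supported, -combined, Inf)
  ord <- order(key, seq_along(regions))
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  class(out) <- c("region_profile", "data.frame")
  out
}
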