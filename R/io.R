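# Tab-delimited writers/readers for the pipeline's tabular outputs.
# All tables are UTF-8, tab-delimited, '.' decimal.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read a cohort table
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return The path (write) or the table (read), invisibly for writes.
#' @export
write_cohort <- function(cohort, path) write_tsv(cohort, path)

#' @rdname write_cohort
#' @export
read_cohort <- function(path) read_tsv(path)

#' Write / read a session design table
#' @param sessions sessions data.frame.
#' @param path file path.
#' @export
write_sessions <- function(sessions, path) write_tsv(sessions, path)

#' @rdname write_sessions
#' @export
read_sessions <- function(path) read_tsv(path)

#' Write an ROI time-series set as one TSV per subject/session
#'
#' Each file has the region labels as header row.
#'
#' @param ts_set \code{roi_ts_set}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_timeseries_set <- function(ts_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (key in names(ts_set$series)) {
    p <- file.path(dir, paste0(key, ".tsv"))
    write_tsv(as.data.frame(ts_set$series[[key]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an ROI time-series set written by [write_timeseries_set()]
#' @param dir directory of per-session TSV files.
#' @return \code{roi_ts_set}.
#' @export
read_timeseries_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no time-series files in ", dir)
  series <- lapply(files, function(f) as.matrix(read_tsv(f)))
  keys <- sub("\\.tsv$", "", basename(files))
  names(series) <- keys
  parts <- regmatches(keys, regexpr("\\.", keys), invert = TRUE)
  structure(list(
    region_labels = colnames(series[[1L]]),
    series = series,
    index = data.frame(
      subject_id = vapply(parts, `[`, character(1), 1L),
      session = vapply(parts, `[`, character(1), 2L),
      key = keys, stringsAsFactors = FALSE)),
    class = "roi_ts_set")
}

#' Write an effect matrix as a TSV trio plus JSON metadata
#'
#' Writes \code{<prefix>_effect.tsv}, \code{<prefix>_t.tsv},
#' \code{<prefix>_p.tsv} (region labels as header and first column) and
#' \code{<prefix>_meta.json} (contrast name, df, sidedness, masked
#' diagonal note).
#'
#' @param em \code{effect_matrix}.
#' @param prefix path prefix.
#' @return Invisibly, the written paths.
#' @export
write_effect_matrix <- function(em, prefix) {
  paths <- character(0)
  for (part in c("effect", "t", "p")) {
    p <- paste0(prefix, "_", part, ".tsv")
    df <- data.frame(region = em$region_labels, em[[part]],
                     check.names = FALSE)
    write_tsv(df, p)
    paths <- c(paths, p)
  }
  meta <- list(contrast_name = em$contrast_name, df = em$df,
               alternative = em$alternative,
               diagonal = "masked (stored as 0; 1 for p)")
  mp <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Read an effect matrix written by [write_effect_matrix()]
#' @param prefix path prefix.
#' @return \code{effect_matrix}.
#' @export
read_effect_matrix <- function(prefix) {
  parts <- lapply(c("effect", "t", "p"), function(part) {
    df <- read_tsv(paste0(prefix, "_", part, ".tsv"))
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$region
    m
  })
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  structure(list(region_labels = rownames(parts[[1L]]),
                 effect = parts[[1L]], t = parts[[2L]], p = parts[[3L]],
                 df = meta$df, contrast_name = meta$contrast_name,
                 alternative = meta$alternative),
            class = "effect_matrix")
}

#' Write a correlation curve as TSV plus JSON
#'
#' \code{<prefix>_curve.tsv} holds (size, n_edges, r);
#' \code{<prefix>_curve.json} holds the AUC, rule, contrast and any
#' permutation summary supplied.
#'
#' @param curve \code{correlation_curve}.
#' @param prefix path prefix.
#' @param perm optional \code{permutation_result} whose p-values are
#'   stored alongside.
#' @return Invisibly, the written paths.
#' @export
write_curve <- function(curve, prefix, perm = NULL) {
  tp <- paste0(prefix, "_curve.tsv")
  write_tsv(data.frame(size = curve$sizes, n_edges = curve$n_edges,
                       r = curve$r_values), tp)
  meta <- list(auc = curve$auc, auc_rule = curve$auc_rule,
               contrast_name = curve$contrast_name)
  if (!is.null(perm)) {
    meta <- c(meta, list(p_raw = perm$p_raw, p_fdr = perm$p_fdr,
                         direction = perm$direction,
                         n_perm = perm$n_perm, seed = perm$seed))
  }
  jp <- paste0(prefix, "_curve.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(tp, jp))
}

#' Read a correlation curve written by [write_curve()]
#' @param prefix path prefix.
#' @return \code{correlation_curve} (AUC recomputed fields preserved).
#' @export
read_curve <- function(prefix) {
  df <- read_tsv(paste0(prefix, "_curve.tsv"))
  meta <- jsonlite::read_json(paste0(prefix, "_curve.json"),
                              simplifyVector = TRUE)
  structure(list(sizes = as.integer(df$size),
                 n_edges = as.integer(df$n_edges),
                 r_values = df$r, auc = meta$auc,
                 auc_rule = meta$auc_rule,
                 degenerate = rep(FALSE, nrow(df)),
                 contrast_name = meta$contrast_name),
            class = "correlation_curve")
}

#' Write a region expression profile table
#' @param profile \code{region_profile}.
#' @param path file path.
#' @export
write_profile <- function(profile, path) write_tsv(profile, path)

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("region_profile", "data.frame")
  out
}

#' Write network definitions as YAML
#' @param networks list of [network_def()] objects.
#' @param path file path.
#' @export
write_networks <- function(networks, path) {
  yaml::write_yaml(lapply(networks, function(n) {
    list(name = n$name, source = n$source, regions = n$regions)
  }), path)
  invisible(path)
}
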