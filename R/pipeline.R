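#' Configuration of an end-to-end pipeline run
#'
#' Bundles the synthetic-data block with the analysis toggles. Exactly
#' one of \code{simulation} (a [sim_config()]) or \code{inputs} (paths to
#' previously written cohort/sessions/time-series tables) must be
#' present.
#'
#' @param simulation [sim_config()] describing the synthetic dataset.
#' @param inputs named list of paths (\code{cohort}, \code{sessions},
#'   \code{timeseries_dir}) for a pre-generated dataset.
#' @param n_perm permutations for the AUC test (floor 100).
#' @param seed master analysis seed (expression and permutation streams
#'   are derived from it); defaults to the simulation seed.
#' @param genes marker gene list for the expression ranking.
#' @param allele_model "additive" or "dominant".
#' @param auc_rule AUC rule for the curve statistic.
#' @param cluster_k number of data-driven networks.
#' @param couple_edge character vector of 2 region names whose
#'   connectivity is coupled into the language symptoms; default the
#'   first two signal regions (or first two regions).
#' @param expression_scores optional named latent region scores for the
#'   expression generator (region name -> score).
#' @param write_timeseries write every per-session time-series TSV
#'   (voluminous; off by default).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(simulation = sim_config(),
                       inputs = NULL,
                       n_perm = 1000L,
                       seed = NULL,
                       genes = c("GRIN1", "PV", "SLC17A7"),
                       allele_model = c("additive", "dominant"),
                       auc_rule = c("sum", "trapezoid"),
                       cluster_k = 6L,
                       couple_edge = NULL,
                       expression_scores = NULL,
                       write_timeseries = FALSE) {
  allele_model <- match.arg(allele_model)
  auc_rule <- match.arg(auc_rule)
  if (is.null(simulation) && is.null(inputs)) {
    stop("either a simulation block or input paths must be present")
  }
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (is.null(seed)) {
    seed <- if (!is.null(simulation)) simulation$seed else 1L
  }
  structure(list(simulation = simulation, inputs = inputs,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 genes = genes, allele_model = allele_model,
                 auc_rule = auc_rule, cluster_k = as.integer(cluster_k),
                 couple_edge = couple_edge,
                 expression_scores = expression_scores,
                 write_timeseries = write_timeseries),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or load),
#' expression profiles, connectivity, second-level GLMs and paired
#' contrasts, expression-ranked correlation curves with the genotype
#' permutation test, functional network connectivity (a-priori sets when
#' resolvable, plus data-driven clustering), and symptom-domain tests —
#' writing every stage's tabular outputs under \code{out_dir} and a
#' machine-readable \code{report.json} whose manifest carries an MD5 hash
#' of every written file. Identical config and seed give a byte-identical
#' report.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return The report, invisibly; \code{report.json} on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  report <- list(seed = config$seed, n_perm = config$n_perm,
                 genes = config$genes, allele_model = config$allele_model,
                 auc_rule = config$auc_rule,
                 package_version = as.character(
                   utils::packageVersion("rankcurve")))

  # --- stage: simulate / load -------------------------------------------
  sim <- config$simulation
  dat <- run_stage("simulate", {
    if (!is.null(sim)) {
      cs <- simulate_cohort(sim)
      yaml::write_yaml(unclass(sim)[setdiff(names(sim), "region_labels")],
                       file.path(out_dir, "sim_config.yaml"))
      files <- c(files, file.path(out_dir, "sim_config.yaml"))
      cs
    } else {
      list(cohort = read_cohort(config$inputs$cohort),
           sessions = read_sessions(config$inputs$sessions))
    }
  })
  write_cohort(dat$cohort, file.path(out_dir, "cohort.tsv"))
  write_sessions(dat$sessions, file.path(out_dir, "sessions.tsv"))
  files <- c(files, file.path(out_dir, c("cohort.tsv", "sessions.tsv")))
  report$simulate <- list(
    n_patients = sum(dat$cohort$group == "patient"),
    n_controls = sum(dat$cohort$group == "control"),
    n_pharmaco = sum(dat$cohort$group == "pharmaco"),
    genotype = as.list(table(dat$cohort$allele_count)))

  region_labels <- if (!is.null(sim)) sim$region_labels else NULL

  # --- stage: expression profiles ---------------------------------------
  prof <- run_stage("profiles", {
    tab <- default_region_table()
    if (!is.null(region_labels)) {
      tab <- tab[tab$name %in% region_labels, , drop = FALSE]
    }
    atlas <- make_synthetic_atlas(tab)
    samples <- simulate_expression_samples(
      atlas, genes = config$genes,
      region_scores = config$expression_scores,
      seed = config$seed + 10L)
    assignment <- assign_samples(samples, atlas)
    profile <- build_profiles(samples, assignment, config$genes,
                              region_table = tab)
    utils::write.csv(samples, file.path(out_dir, "expression_samples.csv"),
                     row.names = FALSE)
    write_profile(profile, file.path(out_dir, "region_profile.tsv"))
    list(atlas = atlas, profile = profile)
  })
  files <- c(files, file.path(out_dir, c("expression_samples.csv",
                                         "region_profile.tsv")))
  report$profiles <- list(
    n_regions = nrow(prof$profile),
    n_supported = sum(prof$profile$supported),
    top_region = prof$profile$region[prof$profile$rank == 1L])

  # --- stage: connectivity ----------------------------------------------
  conn <- run_stage("connect", {
    ts <- if (!is.null(sim)) {
      simulate_timeseries(dat$cohort, dat$sessions, sim)
    } else {
      read_timeseries_set(config$inputs$timeseries_dir)
    }
    if (isTRUE(config$write_timeseries)) {
      files <<- c(files,
                  write_timeseries_set(ts, file.path(out_dir,
                                                     "timeseries")))
    }
    rest_conn <- function(group) {
      ids <- dat$cohort$subject_id[dat$cohort$group %in% group]
      keys <- paste0(ids, ".rest")
      keys <- keys[keys %in% names(ts$series)]
      cl <- lapply(keys, function(k) {
        compute_connectivity(ts$series[[k]], ts$region_labels)
      })
      names(cl) <- sub("\\.rest$", "", keys)
      stack_connectivity(cl)
    }
    list(patients = rest_conn("patient"),
         rest_all = rest_conn(c("patient", "control")),
         pharmaco = connectivity_by_session(
           ts, dat$cohort$subject_id[dat$cohort$group == "pharmaco"]))
  })
  report$connect <- list(
    n_edges = ncol(conn$patients),
    n_patient_matrices = nrow(conn$patients))

  # --- stage: second-level GLMs and contrasts ---------------------------
  glms <- run_stage("glm", {
    design_allele <- make_design(dat$cohort, "allele",
                                 allele_model = config$allele_model)
    design_group <- make_design(dat$cohort, "group")
    snp <- fit_edge_glm(conn$patients, design_allele,
                        contrast_name = "snp")
    sz <- fit_edge_glm(conn$rest_all, design_group,
                       contrast_name = "sz_gt_hc")
    pharm <- lapply(c("ket_gt_pla", "mdz_gt_pla", "ket_gt_mdz"),
                    function(nm) {
                      paired_contrast(conn$pharmaco, contrast_spec(nm))
                    })
    names(pharm) <- c("ket_gt_pla", "mdz_gt_pla", "ket_gt_mdz")
    write_effect_matrix(snp, file.path(out_dir, "snp"))
    for (nm in names(pharm)) {
      write_effect_matrix(pharm[[nm]], file.path(out_dir, nm))
    }
    list(design_allele = design_allele, design_group = design_group,
         snp = snp, sz = sz, pharm = pharm)
  })
  for (nm in c("snp", "ket_gt_pla", "mdz_gt_pla", "ket_gt_mdz")) {
    files <- c(files, paste0(file.path(out_dir, nm),
                             c("_effect.tsv", "_t.tsv", "_p.tsv",
                               "_meta.json")))
  }
  report$glm <- list(df_snp = glms$snp$df,
                     df_paired = glms$pharm[[1L]]$df)

  # --- stage: curves + permutation test ---------------------------------
  perms <- run_stage("curves", {
    permutation_test(conn$patients, glms$design_allele, glms$pharm,
                     prof$profile, n_perm = config$n_perm,
                     seed = config$seed + 20L,
                     auc_rule = config$auc_rule)
  })
  report$curves <- lapply(perms, function(pr) {
    list(auc = pr$observed_auc, direction = pr$direction,
         p_raw = pr$p_raw, p_fdr = pr$p_fdr, n_perm = pr$n_perm)
  })
  for (nm in names(perms)) {
    files <- c(files,
               write_curve(perms[[nm]]$observed_curve,
                           file.path(out_dir, nm), perm = perms[[nm]]))
  }

  # --- stage: functional network connectivity ---------------------------
  fnc <- run_stage("fnc", {
    labels <- attr(conn$patients, "region_labels")
    out <- list()
    nets <- default_networks()
    if (all(c(nets$spt$regions, nets$asm$regions) %in% labels)) {
      out$spt_asm <- fnc_test(conn$patients, glms$design_allele,
                              nets$spt, nets$asm)
    }
    mean_z <- fill_symmetric(colMeans(conn$patients), labels)
    k <- min(config$cluster_k, length(labels) - 1L)
    clustered <- cluster_networks(mean_z, k)
    usable <- clustered[vapply(clustered, function(n) {
      length(n$regions) >= 2L
    }, logical(1))]
    if (length(usable) >= 2L) {
      out$clustered <- fnc_all_pairs(conn$patients, glms$design_allele,
                                     usable)
    }
    write_networks(clustered, file.path(out_dir, "networks.yaml"))
    out$clustered_defs <- clustered
    out
  })
  files <- c(files, file.path(out_dir, "networks.yaml"))
  report$fnc <- list(
    n_clustered = length(fnc$clustered_defs),
    spt_asm = if (!is.null(fnc$spt_asm)) {
      list(effect = fnc$spt_asm$effect, p = fnc$spt_asm$p)
    },
    n_fnc_tests = if (!is.null(fnc$clustered)) nrow(fnc$clustered))
  if (!is.null(fnc$clustered)) {
    write_tsv(fnc$clustered, file.path(out_dir, "fnc_tests.tsv"))
    files <- c(files, file.path(out_dir, "fnc_tests.tsv"))
  }

  # --- stage: symptoms ---------------------------------------------------
  symp <- run_stage("symptoms", {
    if (is.null(sim)) return(NULL)
    labels <- attr(conn$patients, "region_labels")
    edge <- config$couple_edge
    if (is.null(edge)) {
      edge <- if (length(sim$signal_regions) >= 2L) {
        sim$signal_regions[1:2]
      } else {
        labels[1:2]
      }
    }
    col <- edge_column(match(edge[1L], labels), match(edge[2L], labels))
    edge_conn <- conn$patients[, col]
    symptoms <- simulate_symptoms(dat$cohort, edge_conn, sim)
    write_tsv(symptoms, file.path(out_dir, "symptoms.tsv"))
    tests <- symptom_domain_tests(symptoms, dat$cohort)
    list(symptoms = symptoms, tests = tests, edge = edge)
  })
  if (!is.null(symp)) {
    files <- c(files, file.path(out_dir, "symptoms.tsv"))
    report$symptoms <- lapply(symp$tests, function(tst) {
      list(wilks_lambda = tst$wilks_lambda, F = tst$F,
           df1 = tst$df1, df2 = tst$df2, p = tst$p, p_fdr = tst$p_fdr)
    })
    report$symptoms$coupled_edge <- symp$edge
  }

  # --- manifest + report -------------------------------------------------
  hashes <- unname(tools::md5sum(files))
  report$manifest <- data.frame(
    file = sub(paste0("^", gsub("([.|()\\^{}+$*?]|\\[|\\])", "\\\\\\1",
                                out_dir), "/?"), "", files),
    md5 = hashes, stringsAsFactors = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
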