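#' Run the full two-timepoint screening analysis in memory
#'
#' Convenience driver chaining the screening stages: perturbation matrix,
#' significance filter, activity correlations (one family per assay
#' present), peptide-peptide covariation over the kept cells and Ward
#' clustering of compound signatures.
#'
#' @param observations long uptake table (simulated or read from CSV).
#' @param activities activity table, or NULL to skip correlations.
#' @param vehicle control condition id.
#' @param config an [significance_config()].
#' @return object of class \code{hdx_screen} with elements \code{pm},
#'   \code{kept}, \code{correlations} (named list per assay),
#'   \code{covariation}, \code{clustering}.
#' @export
hdx_screen <- function(observations, activities = NULL,
                       vehicle = "vehicle",
                       config = significance_config()) {
  pm <- perturbation_matrix(observations, vehicle = vehicle,
                            config = config)
  kept <- significance_filter(pm, config)
  correlations <- list()
  if (!is.null(activities)) {
    for (assay in intersect(.known_assays, unique(activities$assay)))
      correlations[[assay]] <-
        activity_correlation(pm, activities, assay, kept = kept)
  }
  # covariation and clustering both run on the filtered cells (the
  # reduced dataset that screening heatmaps display); clustering falls
  # back to the full signature when the filter keeps nothing
  cov <- if (nrow(kept$kept) >= 2L) covariation(pm, kept = kept) else NULL
  clus <- if (length(pm$compounds) >= 2L) {
    if (nrow(kept$kept) >= 2L) cluster_compounds(pm, kept = kept)
    else cluster_compounds(pm)
  } else NULL
  structure(list(pm = pm, kept = kept, correlations = correlations,
                 covariation = cov, clustering = clus),
            class = "hdx_screen")
}

#' @export
print.hdx_screen <- function(x, ...) {
  cat("Two-timepoint differential HDX-MS screen\n")
  print(x$pm)
  print(x$kept)
  for (a in names(x$correlations)) {
    cc <- x$correlations[[a]]
    best <- cc[which.max(replace(cc$r_squared, is.na(cc$r_squared), -1)), ]
    cat(sprintf("  %s: best r^2 = %.3f at %s (adjusted p = %.2g)\n",
                a, best$r_squared, best$label, best$adjusted_p))
  }
  if (!is.null(x$clustering))
    cat(sprintf("  Ward tree over %d compounds (%d complete cells)\n",
                length(x$clustering$labels),
                length(x$clustering$signature_cells)))
  invisible(x)
}

#' @export
summary.hdx_screen <- function(object, ...) {
  print(object)
  invisible(object)
}

.default_run_config <- function() {
  list(workflow = "screen", seed = 1L, vehicle = "vehicle",
       output_dir = "hdx-output", log_level = "info",
       paths = list(uptake_table = NULL, activity_table = NULL,
                    sequence_fasta = NULL),
       significance = list(), simulate = NULL)
}

.log <- function(level, cfg_level, ...) {
  ranks <- c(debug = 1, info = 2, warn = 3)
  if (ranks[[level]] >= ranks[[cfg_level %||% "info"]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured workflow end to end
#'
#' Drives either the full time-course differential workflow
#' (\code{workflow: timecourse} -- uptake curves, perturbation records,
#' mean-over-timepoints residue consolidation, per-residue exports) or the
#' two-timepoint screening workflow (\code{workflow: screen} --
#' perturbation matrix, significance filter, activity correlations,
#' covariation grid, Ward linkage table). Inputs come from the configured
#' CSV paths, or from the built-in simulator when a \code{simulate} block
#' is present. Every file written is listed in the returned manifest with
#' its row count; the configuration, seed and package version are logged.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognised fields: \code{workflow} ("timecourse" or "screen"),
#'   \code{seed}, \code{vehicle}, \code{output_dir}, \code{log_level},
#'   \code{paths} (uptake_table, activity_table, sequence_fasta),
#'   \code{significance} (arguments of [significance_config()]) and
#'   \code{simulate} (arguments of [simulate_screen_inputs()]).
#' @return object of class \code{hdx_workflow}: list with \code{status}
#'   (0 on success), \code{manifest} (data.frame file/rows),
#'   \code{results} (the in-memory stage objects), invisibly.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_run_config(), config)
  lv <- cfg$log_level
  if (!cfg$workflow %in% c("timecourse", "screen"))
    stop("workflow must be 'timecourse' or 'screen'")
  sig <- do.call(significance_config, cfg$significance)
  # config errors must fire before anything touches the filesystem
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$paths$uptake_table))
      stop("config error: paths$uptake_table is required unless simulating")
    if (cfg$workflow == "screen" && is.null(cfg$paths$activity_table))
      stop("config error: screen workflow requires paths$activity_table")
  }
  .log("info", lv, "hdxscreen ",
       as.character(utils::packageVersion("hdxscreen")),
       " | workflow=", cfg$workflow, " seed=", cfg$seed)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), rows = integer(0))
  add <- function(path, rows) {
    manifest <<- rbind(manifest,
                       data.frame(file = basename(path), rows = rows))
  }
  # --- inputs -------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    .log("info", lv, "simulating inputs")
    sim_args <- cfg$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sim_args$timecourse <- cfg$workflow == "timecourse"
    sim <- do.call(simulate_screen_inputs, sim_args)
    obs <- sim$observations
    act <- sim$activities
    up_path <- file.path(cfg$output_dir, "uptake.csv")
    write_uptake_table(obs, up_path); add(up_path, nrow(obs))
    ac_path <- file.path(cfg$output_dir, "activities.csv")
    write_activity_table(act, ac_path); add(ac_path, nrow(act))
    peptides <- sim$peptides
  } else {
    inp <- read_uptake_table(cfg$paths$uptake_table)
    obs <- inp$observations
    peptides <- inp$peptides
    act <- if (cfg$workflow == "screen")
      read_activity_table(cfg$paths$activity_table) else NULL
  }
  results <- list(peptides = peptides)
  # --- stages -------------------------------------------------------
  if (cfg$workflow == "timecourse") {
    .log("info", lv, "building uptake curves")
    curves <- build_uptake_curves(obs)
    p <- file.path(cfg$output_dir, "uptake_curves.csv")
    .write_csv(as.data.frame(curves), p); add(p, nrow(curves))
    .log("info", lv, "computing perturbations")
    pm <- perturbation_matrix(obs, vehicle = cfg$vehicle, config = sig)
    write_perturbation_tables(
      pm, file.path(cfg$output_dir, "perturbations.csv"), NULL)
    add("perturbations.csv", nrow(pm$records))
    .log("info", lv, "consolidating to residues")
    residue_maps <- list()
    for (cmp in pm$compounds) {
      mp <- mean_perturbation(pm, cmp)
      v <- setNames(mp$mean_delta, mp$peptide_id)
      rm_ <- consolidate_to_residues(v, peptides)
      residue_maps[[cmp]] <- rm_
      p <- file.path(cfg$output_dir,
                     paste0("residues_", cmp, ".csv"))
      .write_csv(as.data.frame(rm_), p); add(p, nrow(rm_))
      write_attribute_list(
        rm_, file.path(cfg$output_dir, paste0("attr_", cmp, ".csv")))
      add(paste0("attr_", cmp, ".csv"), sum(!rm_$missing))
    }
    results <- c(results, list(curves = curves, pm = pm,
                               residue_maps = residue_maps))
  } else {
    .log("info", lv, "running screen")
    scr <- hdx_screen(obs, act, vehicle = cfg$vehicle, config = sig)
    write_perturbation_tables(
      scr$pm, file.path(cfg$output_dir, "perturbations.csv"),
      file.path(cfg$output_dir, "perturbation_matrix.csv"))
    add("perturbations.csv", nrow(scr$pm$records))
    add("perturbation_matrix.csv", nrow(scr$pm$delta))
    p <- file.path(cfg$output_dir, "kept_cells.csv")
    .write_csv(scr$kept$kept, p); add(p, nrow(scr$kept$kept))
    for (a in names(scr$correlations)) {
      p <- file.path(cfg$output_dir, paste0("correlation_", a, ".csv"))
      .write_csv(as.data.frame(scr$correlations[[a]]), p)
      add(p, nrow(scr$correlations[[a]]))
    }
    if (!is.null(scr$covariation)) {
      p <- file.path(cfg$output_dir, "covariation_grid.csv")
      utils::write.csv(signif(scr$covariation$r2, 6), p)
      add(p, nrow(scr$covariation$r2))
      p <- file.path(cfg$output_dir, "covariation_mask.csv")
      utils::write.csv(scr$covariation$mask, p)
      add(p, nrow(scr$covariation$mask))
    }
    if (!is.null(scr$clustering)) {
      link <- data.frame(merge1 = scr$clustering$merge[, 1],
                         merge2 = scr$clustering$merge[, 2],
                         height = scr$clustering$height)
      p <- file.path(cfg$output_dir, "linkage.csv")
      .write_csv(link, p); add(p, nrow(link))
    }
    results <- c(results, list(screen = scr))
  }
  p <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE)
  .log("info", lv, "wrote ", nrow(manifest), " files to ",
       cfg$output_dir)
  invisible(structure(list(status = 0L, manifest = manifest,
                           results = results, config = cfg),
                      class = "hdx_workflow"))
}

#' @export
print.hdx_workflow <- function(x, ...) {
  cat("HDX workflow (", x$config$workflow, "): status ", x$status,
      "\n", sep = "")
  print.data.frame(x$manifest)
  invisible(x)
}

#' Simulate complete screening (or time-course) inputs
#'
#' One-call front end to the generator: builds the synthetic protein, the
#' overlapping peptide map, a compound library with planted
#' pharmacological classes, replicate uptake observations and coupled
#' functional-assay activities. All randomness derives from \code{seed}.
#'
#' @param n_compounds library size.
#' @param class_proportions passed to [simulate_compound_library()].
#' @param n_replicates replicates per condition-timepoint (default 5, the
#'   screening design; the time-course default is 3).
#' @param noise_sd replicate noise SD in percentage points.
#' @param timecourse use the 8-point time course instead of the
#'   two-timepoint (10 s, 4 hr) screening design.
#' @param n_peptides,target_coverage peptide-map preset.
#' @param link an [assay_link_model()], or NULL to skip activities.
#' @param seed master integer seed.
#' @return list with \code{protein}, \code{peptides}, \code{compounds},
#'   \code{observations}, \code{activities}, \code{config}.
#' @export
simulate_screen_inputs <- function(n_compounds = 38L,
                                   class_proportions = c(
                                     agonist = 13 / 38,
                                     partial_agonist = 12 / 38,
                                     inverse_agonist = 13 / 38),
                                   n_replicates = NULL, noise_sd = 1.5,
                                   timecourse = FALSE, n_peptides = 54L,
                                   target_coverage = 0.98,
                                   link = assay_link_model(),
                                   seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(n_replicates)) n_replicates <- if (timecourse) 3L else 5L
  tp <- if (timecourse) c(0, 10, 30, 110, 380, 1270, 4270, 14400)
        else c(10, 14400)
  protein <- synthetic_protein(seed = seed)
  peptides <- generate_peptide_map(protein, n_peptides = n_peptides,
                                   target_coverage = target_coverage,
                                   seed = seed + 1L)
  compounds <- simulate_compound_library(
    n = n_compounds, class_proportions = class_proportions,
    seed = seed + 2L)
  cfg <- sim_config(timepoints = tp, n_replicates = n_replicates,
                    noise_sd = noise_sd, seed = seed + 3L)
  obs <- simulate_hdx_dataset(protein, peptides, compounds, cfg)
  act <- if (is.null(link)) NULL else
    simulate_activities(protein, compounds, link, seed = seed + 4L)
  list(protein = protein, peptides = peptides, compounds = compounds,
       observations = obs, activities = act, config = cfg)
}
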