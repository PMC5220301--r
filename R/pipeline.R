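# Config-driven end-to-end orchestration: poses -> cluster -> filter ->
# characterize -> alanine scan, plus optional thermodynamics, coevolution
# and spatial-statistics stages. Deterministic under a fixed config + seed.

#' Default run configuration
#'
#' Every threshold defaults to the conventional value used throughout the
#' package: 0.14 nm SASA probe, 0.3 nm / 20 deg hydrogen bonds, 0.38 nm
#' hydrophobic contacts, 0.4 nm cluster radius, 5% enrichment cutoff,
#' co-evolution score 2.0, exposure 0.25, T = 300 K, 4.6 nm reference
#' separation.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1,
    out_dir = "dimerscope_run",
    poses = NULL,                  # path to multi-model PDB / directory
    chains_a = "A", chains_b = "B",
    synthetic_poses = TRUE,        # use the synthetic scenario when no path
    n_poses = 100,
    hotspots = c(94, 95, 97, 98, 101, 102, 107),
    reactive_surfaces = integer(0),
    effector_loop = c(25, 40),
    anchor_resid = 140,
    promote_clusters = integer(0),
    probe_radius = 0.14,
    n_sphere_points = 240,
    hb_d_cut = 0.30, hb_angle_cut = 20,
    hc_d_cut = 0.38,
    salt_bridge_cut = 0.40,
    cluster_radius = 0.40,
    min_enrichment = 0.05,
    score_cut = 2.0,
    exposure_cut = 0.25,
    temperature = 300,
    reference_from = 4.6,
    mean_force = NULL,             # path to 3-column TSV
    msa = NULL,                    # path to aligned FASTA / Stockholm
    coupling_table = NULL,         # path to i/j/score TSV
    patterns_a = NULL, patterns_b = NULL  # point-pattern TSV paths
  )
}

#' Load, validate and save run configurations (YAML)
#'
#' Unknown keys are rejected; missing keys take their defaults. The
#' round-trip through [write_run_config()] and [read_run_config()] is
#' lossless.
#'
#' @param config named list (possibly partial).
#' @return validated full configuration list.
#' @export
validate_config <- function(config) {
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- def
  out[names(config)] <- config
  # YAML round-trips empty/integer vectors as lists; normalize
  for (nm in c("hotspots", "reactive_surfaces", "promote_clusters"))
    if (!is.character(out[[nm]]))
      out[[nm]] <- as.integer(unlist(out[[nm]]))
  out$effector_loop <- as.numeric(unlist(out$effector_loop))
  stopifnot(out$probe_radius > 0, out$cluster_radius > 0,
            out$min_enrichment >= 0, out$temperature > 0)
  out
}

#' @rdname validate_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname validate_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}

run_stage <- function(name, log_con, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  msg <- sprintf("[%s] stage %-14s done in %.1f s", format(Sys.time()),
                 name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(msg, log_con)
  message(msg)
  res
}

#' Run the full dimer-prediction pipeline
#'
#' Poses are loaded (or generated synthetically), clustered, passed through
#' the three viability filters; every surviving representative gets an
#' interface report and an alanine scan. Optional stages run when their
#' inputs are configured: PMF thermodynamics from a mean-force table,
#' co-evolution scoring from an MSA or coupling table, and Ripley
#' K-statistics on point-pattern groups. All outputs (audit TSV, JSON
#' reports, log with config hash and seed) go to `config$out_dir`;
#' rerunning with the same config reproduces them.
#'
#' @param config configuration list (see [default_config()]), or a YAML
#'   path.
#' @return list with `audit`, `survivors`, `reports` (per-survivor
#'   interface reports), `scans`, and optional `binding`, `coevolution`,
#'   `spatial`; plus `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, null = "null")
  writeLines(c(sprintf("dimerscope %s", as.character(utils::packageVersion("dimerscope"))),
               sprintf("seed %d", config$seed),
               sprintf("config sha %s", substr(digest_string(cfg_json), 1, 12))),
             log_con)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)

  # --- poses: load or synthesize -------------------------------------------
  truth <- NULL
  ensemble <- run_stage("poses", log_con, {
    if (!is.null(config$poses)) {
      read_pose_ensemble(config$poses, config$chains_a, config$chains_b)
    } else if (isTRUE(config$synthetic_poses)) {
      syn <- synth_pose_ensemble(pose_plan(n_poses = config$n_poses,
                                           seed = config$seed))
      truth <<- syn$truth
      syn$ensemble
    } else stop("no pose input configured")
  })

  result <- list(out_dir = config$out_dir)
  if (length(ensemble$poses) >= 2) {
    clusters <- run_stage("cluster", log_con, {
      M <- pairwise_pose_rmsd(ensemble)
      cluster_poses(M, config$cluster_radius, config$min_enrichment)
    })
    audit <- run_stage("filter", log_con, {
      hot <- if (is.character(config$hotspots))
        read_residue_list(config$hotspots) else config$hotspots
      reac <- if (is.character(config$reactive_surfaces))
        read_residue_list(config$reactive_surfaces) else config$reactive_surfaces
      apply_filters(clusters, ensemble, hotspots = hot,
                    reactive_surfaces = reac,
                    effector_loop = config$effector_loop[1]:config$effector_loop[2],
                    anchor_resid = config$anchor_resid,
                    promote = config$promote_clusters,
                    exposure_cut = config$exposure_cut,
                    n_sphere_points = config$n_sphere_points)
    })
    write_audit_tsv(audit, file.path(config$out_dir, "filter_audit.tsv"))
    result$clusters <- clusters
    result$audit <- audit$audit
    result$survivors <- audit$survivors

    reports <- list(); scans <- list()
    if (length(audit$poses)) {
      run_stage("characterize", log_con, {
        for (k in seq_along(audit$poses)) {
          pose <- audit$poses[[k]]
          rep_k <- interface_report(pose,
                                    probe_radius = config$probe_radius,
                                    n_sphere_points = config$n_sphere_points)
          write_interface_report(
            rep_k,
            tsv_path = file.path(config$out_dir,
                                 sprintf("interface_c%d.tsv",
                                         audit$survivors[k])),
            json_path = file.path(config$out_dir,
                                  sprintf("interface_c%d.json",
                                          audit$survivors[k])))
          reports[[k]] <- rep_k
          sc <- scan_interface(pose,
                               n_sphere_points = config$n_sphere_points)
          write_scan_tsv(sc, file.path(config$out_dir,
                                       sprintf("alascan_c%d.tsv",
                                               audit$survivors[k])))
          scans[[k]] <- sc
        }
      })
    }
    result$reports <- reports
    result$scans <- scans
    if (!is.null(truth)) result$truth <- truth
  }

  # --- optional stages ------------------------------------------------------
  if (!is.null(config$mean_force)) {
    result$binding <- run_stage("thermodynamics", log_con, {
      prof <- read_mean_force(config$mean_force)
      pmf <- integrate_mean_force(prof, config$reference_from)
      write_profile_tsv(pmf, file.path(config$out_dir, "pmf.tsv"))
      est <- kd_from_pmf(pmf, temperature = config$temperature,
                         force_stderr = prof$stderr)
      jsonlite::write_json(
        list(kd_molar = est$kd, dg_kcal_mol = est$dg,
             kd_stderr = est$kd_stderr, temperature = est$temperature,
             bound_window_nm = est$bound_window),
        file.path(config$out_dir, "binding.json"), auto_unbox = TRUE,
        digits = NA)
      est
    })
  }
  if (!is.null(config$msa) || !is.null(config$coupling_table)) {
    result$coevolution <- run_stage("coevolve", log_con, {
      cmap <- if (!is.null(config$coupling_table))
        read_coupling_table(config$coupling_table)
      else coevolution_scores(read_msa(config$msa))
      write_coevolution_tsv(cmap, pairs_path =
                              file.path(config$out_dir, "coevolution.tsv"))
      cmap
    })
  }
  if (!is.null(config$patterns_a) && !is.null(config$patterns_b)) {
    result$spatial <- run_stage("ripley", log_con, {
      ga <- lapply(config$patterns_a, read_point_pattern)
      gb <- lapply(config$patterns_b, read_point_pattern)
      bt <- bootstrap_compare(ga, gb, seed = config$seed)
      jsonlite::write_json(bt, file.path(config$out_dir, "ripley.json"),
                           auto_unbox = TRUE, digits = NA)
      bt
    })
  }

  summary <- list(
    n_poses = length(ensemble$poses),
    n_clusters = if (!is.null(result$clusters)) nrow(result$clusters$clusters)
      else NA,
    survivors = result$survivors)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(sprintf("[%s] pipeline complete: %d survivor(s)",
                     format(Sys.time()), length(result$survivors)), log_con)
  invisible(result)
}

# small stable string hash (polynomial rolling; provenance only)
digest_string <- function(s) {
  v <- utf8ToInt(paste(s, collapse = ""))
  h1 <- 0; h2 <- 0
  for (x in v) {
    h1 <- (h1 * 31 + x) %% 2147483647
    h2 <- (h2 * 131 + x) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}
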