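#' Read and validate an analysis configuration
#'
#' A single structured YAML file drives the comparative two-state analysis.
#' Top-level keys: `topology` (PDB path), `parameters` (optional sidecar
#' nonbonded-parameter table), `domain_map` (YAML), `trajectories` (mapping
#' of state tag, e.g. `PD`/`PL`, to a list of replica trajectory paths),
#' `temperature` (K, default 300), `discard_fraction` (default 0.10),
#' `pool` (`"frames"`: pool replicas after per-replica windowing, the
#' default; `"average"`: average per-replica results), `output_dir`, `seed`,
#' and per-stage blocks `entropy`, `fda`, `geometry` (see the vignette for
#' the full schema). Relative paths are resolved against the config file's
#' directory.
#'
#' @param path YAML configuration file.
#' @return A validated config list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  if (is.null(cfg$topology)) stop("config needs a 'topology' path")
  cfg$topology <- resolve(cfg$topology)
  cfg$parameters <- resolve(cfg$parameters)
  cfg$domain_map <- resolve(cfg$domain_map)
  if (is.null(cfg$trajectories) || length(cfg$trajectories) == 0) {
    stop("config needs at least one state under 'trajectories'")
  }
  cfg$trajectories <- lapply(cfg$trajectories, function(x) {
    vapply(x, resolve, character(1))
  })
  for (f in c(cfg$topology, cfg$parameters, cfg$domain_map,
              unlist(cfg$trajectories))) {
    if (!file.exists(f)) stop("configured path does not exist: ", f)
  }
  cfg$temperature <- cfg$temperature %||% .default_temperature
  if (cfg$temperature <= 0) stop("temperature must be > 0")
  cfg$discard_fraction <- cfg$discard_fraction %||% 0.10
  cfg$pool <- cfg$pool %||% "frames"
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg$seed <- cfg$seed %||% 1L
  cfg$entropy <- cfg$entropy %||% list()
  cfg$fda <- cfg$fda %||% list()
  cfg$geometry <- cfg$geometry %||% list()
  class(cfg) <- "analysis_config"
  cfg
}

# Load topology (+ parameters), domain map, and per-state pooled
# trajectories with the equilibration rule applied per replica.
load_inputs <- function(cfg) {
  st <- read_structure(cfg$topology)
  top <- st$topology
  if (!is.null(cfg$parameters)) top <- read_parameters(top, cfg$parameters)
  map <- if (!is.null(cfg$domain_map)) read_domain_map(cfg$domain_map)
         else default_domain_map()
  states <- lapply(cfg$trajectories, function(paths) {
    reps <- lapply(paths, function(p) {
      discard_equilibration(read_trajectory(p, top), cfg$discard_fraction)
    })
    list(replicas = reps, pooled = pool_trajectories(reps))
  })
  list(topology = top, map = map, states = states, reference = st$trajectory)
}

#' Pool replica trajectories into one frame set
#'
#' Concatenates the frames of several (already windowed) replicas; times are
#' re-offset so they remain strictly increasing. Ensemble averages over the
#' pooled set weight every frame equally.
#'
#' @param replicas List of [trajectory()] objects with equal atom counts.
#' @return A single [trajectory()].
#' @export
pool_trajectories <- function(replicas) {
  if (length(replicas) == 1) return(replicas[[1]])
  na <- unique(vapply(replicas, function(t) dim(t$coords)[2], numeric(1)))
  if (length(na) != 1) stop("replicas differ in atom count")
  coords <- do.call(abind_frames, replicas)
  t0 <- 0
  times <- numeric(0)
  for (tr in replicas) {
    tt <- tr$times - tr$times[1]
    dt <- if (length(tt) > 1) tt[2] - tt[1] else 1
    times <- c(times, t0 + tt)
    t0 <- t0 + (if (length(tt) > 1) tt[length(tt)] else 0) + dt
  }
  trajectory(coords, times)
}

abind_frames <- function(...) {
  lst <- list(...)
  nf <- sum(vapply(lst, n_frames, numeric(1)))
  na <- dim(lst[[1]]$coords)[2]
  out <- array(NA_real_, dim = c(nf, na, 3))
  at <- 0
  for (tr in lst) {
    k <- n_frames(tr)
    out[at + seq_len(k), , ] <- tr$coords
    at <- at + k
  }
  out
}

stage_file <- function(cfg, name) file.path(cfg$output_dir, name)

write_stage_output <- function(x, cfg, name, manifest, dry_run) {
  if (dry_run) return(manifest)
  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
  }
  path <- stage_file(cfg, name)
  write_result_tsv(x, path)
  c(manifest, path)
}

#' Run the entropy stage of the comparative analysis
#'
#' Computes per-domain configurational entropies for each state, the
#' state-difference column `delta_S = S_state2 - S_state1` (states in config
#' order, e.g. peptide-loaded minus peptide-deficient), and uncertainties
#' from the final-10%-of-cumulative-sampling rule. When the config supplies
#' a solvent entropy change (`entropy$delta_s_solv`, J/(K mol)), a totals
#' row combining the whole-complex configurational change with the solvent
#' term is appended.
#'
#' @param cfg An `analysis_config` (or path to one).
#' @param inputs Optional pre-loaded inputs (from an earlier stage) to avoid
#'   re-reading files.
#' @param dry_run If `TRUE`, compute but write nothing.
#' @return List: `table` (tidy entropy table), `per_state` (list of
#'   `entropy_result`), `manifest` (files written).
#' @export
run_entropy_stage <- function(cfg, inputs = NULL, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  if (is.null(inputs)) inputs <- load_inputs(cfg)
  fit <- cfg$entropy$fit %||% "per_domain"
  per_state <- lapply(inputs$states, function(s) {
    traj <- if (cfg$pool == "frames") s$pooled else s$pooled
    entropy_by_domain(traj, inputs$topology, inputs$map,
                      temperature = cfg$temperature, fit = fit)
  })
  tab <- NULL
  states <- names(per_state)
  if (length(states) >= 2) {
    s1 <- tidy(per_state[[1]]); s2 <- tidy(per_state[[2]])
    tab <- dplyr::inner_join(
      s1[, c("selection", "S_config", "uncertainty")],
      s2[, c("selection", "S_config", "uncertainty")],
      by = "selection", suffix = paste0("_", states[1:2]))
    tab$delta_S <- tab[[paste0("S_config_", states[2])]] -
      tab[[paste0("S_config_", states[1])]]
    tab$delta_S_unc <- tab[[paste0("uncertainty_", states[1])]] +
      tab[[paste0("uncertainty_", states[2])]]
    solv <- cfg$entropy$delta_s_solv
    if (!is.null(solv)) {
      whole <- tab[tab$selection == "whole", , drop = FALSE]
      if (nrow(whole) == 1) {
        total_row <- whole
        total_row$selection <- "total(config+solvent)"
        total_row$delta_S <- total_entropy(whole$delta_S, solv)
        tab <- dplyr::bind_rows(tab, total_row)
      }
    }
  } else {
    warning("single state: absolute entropies only, no difference column")
    tab <- tidy(per_state[[1]])
  }
  manifest <- character(0)
  manifest <- write_stage_output(tab, cfg, "entropy_table.tsv", manifest,
                                 dry_run)
  list(table = tab, per_state = per_state, manifest = manifest)
}

#' Run the pairwise-force stage
#'
#' Per state, the residue-pair force table between the two configured groups
#' (each a list of domain-map selection names, e.g. group 1 = tapasin TN +
#' peptide, group 2 = MHC I alpha1 + alpha2), thresholded and sorted by
#' magnitude, plus the state-difference table.
#'
#' @inheritParams run_entropy_stage
#' @return List: `per_state` tables, `delta` table, `manifest`.
#' @export
run_fda_stage <- function(cfg, inputs = NULL, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  if (is.null(inputs)) inputs <- load_inputs(cfg)
  top <- inputs$topology
  if (is.null(top$charge)) {
    stop("force analysis needs nonbonded parameters; set 'parameters' ",
         "in the config")
  }
  g1names <- cfg$fda$group1 %||% c("TN", "Ag")
  g2names <- cfg$fda$group2 %||% c("alpha1", "alpha2")
  g1 <- sort(unique(unlist(lapply(g1names, resolve_selection,
                                  map = inputs$map, topology = top))))
  g2 <- sort(unique(unlist(lapply(g2names, resolve_selection,
                                  map = inputs$map, topology = top))))
  params <- nonbonded_params(cutoff = cfg$fda$cutoff %||% 10)
  threshold <- cfg$fda$threshold %||% 200
  convention <- cfg$fda$convention %||% "scalar_sum"
  per_state <- lapply(inputs$states, function(s) {
    residue_pair_forces(s$pooled, top, g1, g2, params,
                        threshold = threshold, convention = convention)
  })
  delta <- if (length(per_state) >= 2) {
    delta_force_table(per_state[[1]], per_state[[2]])
  }
  manifest <- character(0)
  for (st in names(per_state)) {
    manifest <- write_stage_output(per_state[[st]], cfg,
                                   paste0("forces_", st, ".tsv"),
                                   manifest, dry_run)
  }
  if (!is.null(delta)) {
    manifest <- write_stage_output(delta, cfg, "forces_delta.tsv",
                                   manifest, dry_run)
  }
  list(per_state = per_state, delta = delta, manifest = manifest)
}

#' Run the geometry stage
#'
#' Buried interface surface between two configured groups, named distances
#' (e.g. groove widths), fit/measure RMSD, RMSF profiles, and histograms,
#' with the equilibration window already applied by the loader and moving
#' averages as configured.
#'
#' @inheritParams run_entropy_stage
#' @return List of per-state result tibbles plus `manifest`.
#' @export
run_geometry_stage <- function(cfg, inputs = NULL, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  if (is.null(inputs)) inputs <- load_inputs(cfg)
  top <- inputs$topology
  gcfg <- cfg$geometry
  manifest <- character(0)
  out <- list()
  for (st in names(inputs$states)) {
    traj <- inputs$states[[st]]$pooled
    if (!is.null(gcfg$buried)) {
      ga <- resolve_selection(inputs$map, gcfg$buried$group_a, top)
      gb <- resolve_selection(inputs$map, gcfg$buried$group_b, top)
      bs <- buried_surface(traj, top, ga, gb,
                           n_points = gcfg$sas_points %||% 240)
      out[[paste0("buried_", st)]] <- bs
      manifest <- write_stage_output(bs, cfg, paste0("buried_", st, ".tsv"),
                                     manifest, dry_run)
      hist_tab <- series_histogram(bs)
      manifest <- write_stage_output(hist_tab, cfg,
                                     paste0("buried_", st, "_hist.tsv"),
                                     manifest, dry_run)
    }
    if (!is.null(gcfg$distances)) {
      pairs <- dplyr::bind_rows(lapply(gcfg$distances, tibble::as_tibble))
      dd <- named_distances(traj, top, pairs)
      out[[paste0("distances_", st)]] <- dd
      manifest <- write_stage_output(dd, cfg,
                                     paste0("distances_", st, ".tsv"),
                                     manifest, dry_run)
    }
    if (!is.null(gcfg$rmsd)) {
      fit_idx <- resolve_selection(inputs$map, gcfg$rmsd$fit, top, "CA")
      meas_idx <- resolve_selection(inputs$map, gcfg$rmsd$measure, top, "CA")
      rs <- rmsd_series(traj, fit_idx, meas_idx,
                        reference = frame_coords(inputs$reference, 1))
      if (!is.null(gcfg$moving_average_ps)) {
        rs_sm <- moving_average(rs, gcfg$moving_average_ps)
        out[[paste0("rmsd_smooth_", st)]] <- rs_sm
      }
      out[[paste0("rmsd_", st)]] <- rs
      manifest <- write_stage_output(rs, cfg, paste0("rmsd_", st, ".tsv"),
                                     manifest, dry_run)
      if (!is.null(gcfg$rmsd$threshold)) {
        out[[paste0("rmsd_fraction_below_", st)]] <-
          fraction_below(rs, gcfg$rmsd$threshold)
      }
    }
    if (!is.null(gcfg$rmsf)) {
      for (selname in gcfg$rmsf) {
        idx <- resolve_selection(inputs$map, selname, top, "CA")
        rp <- rmsf_profile(traj, idx, topology = top)
        out[[paste0("rmsf_", selname, "_", st)]] <- rp
        manifest <- write_stage_output(
          rp, cfg, paste0("rmsf_", selname, "_", st, ".tsv"),
          manifest, dry_run)
      }
    }
  }
  c(out, list(manifest = manifest))
}

#' Run every configured stage
#'
#' @inheritParams run_entropy_stage
#' @return List with `entropy`, `fda`, `geometry` stage results and a
#'   `report` (per-stage status, file manifest, config echo, package
#'   version).
#' @export
run_all <- function(cfg, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- read_analysis_config(cfg)
  inputs <- load_inputs(cfg)
  status <- list()
  res <- list()
  run_one <- function(name, fun) {
    t0 <- Sys.time()
    r <- tryCatch(fun(cfg, inputs, dry_run = dry_run),
                  error = function(e) e)
    status[[name]] <<- list(
      ok = !inherits(r, "error"),
      message = if (inherits(r, "error")) conditionMessage(r) else "ok",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (!inherits(r, "error")) res[[name]] <<- r
  }
  run_one("entropy", run_entropy_stage)
  if (!is.null(cfg$parameters)) run_one("fda", run_fda_stage)
  run_one("geometry", run_geometry_stage)
  manifest <- unlist(lapply(res, `[[`, "manifest"))
  res$report <- list(
    status = status,
    manifest = unname(manifest %||% character(0)),
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("tidytraj"))
  )
  res
}
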