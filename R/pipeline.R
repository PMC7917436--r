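#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults, rejects unknown keys (naming
#' the offending key) and checks stage parameters. One configuration drives
#' all variants so that the cross-variant comparison uses identical
#' parameters; by default the variants also share the RNG seed, so the
#' comparison is paired (common random numbers) and mean differences are
#' estimated without between-variant sampling noise.
#'
#' @param path YAML file path.
#' @return object of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  top_known <- c("seed", "output_dir", "thresholds", "pca", "clustering",
                 "representatives", "spectra", "variants")
  check_keys(raw, top_known, "top level")
  cfg <- list(
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir %||% NULL,
    thresholds = fill_section(raw$thresholds,
                              list(in_max = 4.0, out_min = 5.0), "thresholds"),
    pca = fill_section(raw$pca, list(variance_target = 0.9), "pca"),
    clustering = fill_section(raw$clustering,
                              list(min_cluster_size_frac = 0.01,
                                   min_population = 0.01), "clustering"),
    representatives = raw$representatives %||% 10L,
    spectra = fill_section(raw$spectra,
                           list(temperature = 300, broadening = 100,
                                shift = -3500), "spectra"))
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("seed must be an integer")
  if (cfg$thresholds$in_max > cfg$thresholds$out_min)
    stop("thresholds: in_max must not exceed out_min")
  if (cfg$spectra$broadening <= 0)
    stop("spectra: broadening must be positive")
  if (cfg$spectra$temperature < 0)
    stop("spectra: temperature must be non-negative")
  if (cfg$pca$variance_target <= 0 || cfg$pca$variance_target > 1)
    stop("pca: variance_target must be in (0, 1]")
  if (is.null(raw$variants) || length(raw$variants) == 0)
    stop("at least one variant is required")
  cfg$variants <- lapply(raw$variants, function(v) {
    check_keys(v, c("name", "seed", "simulate", "crowding"), "variant")
    if (is.null(v$name)) stop("every variant needs a name")
    if (is.null(v$simulate)) stop("variant ", v$name, ": simulate block required")
    check_keys(v$simulate,
               c("n_frames", "frame_spacing", "energy_model", "class_dwell",
                 "classes", "residues", "stable_distances", "mode_set"),
               paste0("variant ", v$name, " simulate"))
    if (!is.null(v$crowding))
      check_keys(v$crowding,
                 c("n_frames", "separation", "separation_sd", "ring_jitter_sd"),
                 paste0("variant ", v$name, " crowding"))
    v
  })
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown key '", unknown[1], "' in ", where)
  invisible(x)
}

fill_section <- function(x, defaults, where) {
  x <- x %||% list()
  check_keys(x, names(defaults), where)
  utils::modifyList(defaults, x)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg[setdiff(names(cfg), "hash")], tf)
  unname(tools::md5sum(tf))
}

#' Run the full pocket-dynamics / spectroscopy pipeline
#'
#' Executes, for every configured variant: synthetic trajectory generation,
#' distance recomputation from the emitted coordinates, in/out state
#' classification, PCA + density clustering with the population filter,
#' IN/OUT cluster labeling, representative sampling, crowding overlap and
#' ring-RMSD observables (when configured), electronic records on the
#' representatives, per-cluster and weighted spectra, and the Stokes table.
#' Stage outputs are written under `output_dir` (when set), each file tagged
#' with the configuration hash.
#'
#' @param config a [validate_config()] result, or a path to a YAML file.
#' @return a `comparison_report`: per-variant results plus cross-variant
#'   deltas (first variant minus second) when two variants are configured.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  results <- lapply(config$variants, function(v)
    run_variant(v, config, out_dir))
  names(results) <- vapply(config$variants, `[[`, "", "name")

  report <- list(variants = results, config_hash = config$hash)
  if (length(results) == 2) {
    a <- results[[1]]; b <- results[[2]]
    delta <- list(
      ss_cm1 = a$stokes$ss_cm1[a$stokes$cluster == "avg"] -
               b$stokes$ss_cm1[b$stokes$cluster == "avg"])
    if (!is.null(a$crowding) && !is.null(b$crowding)) {
      delta$mean_overlap <- a$crowding$mean_overlap - b$crowding$mean_overlap
      delta$mean_ring_rmsd <- a$crowding$mean_ring_rmsd -
                              b$crowding$mean_ring_rmsd
    }
    report$delta <- delta
  }
  if (!is.null(out_dir))
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(report, class = "comparison_report")
}

run_variant <- function(v, config, out_dir) {
  seed <- v$seed %||% config$seed
  sim <- v$simulate
  args <- list(n_frames = sim$n_frames,
               frame_spacing = sim$frame_spacing %||% 1,
               seed = seed)
  for (nm in c("energy_model", "class_dwell", "classes", "residues",
               "stable_distances"))
    if (!is.null(sim[[nm]])) args[[nm]] <- sim[[nm]]
  if (!is.null(sim$mode_set)) args$mode_set <- as.data.frame(sim$mode_set)
  scfg <- do.call(synthetic_config, args)
  traj <- generate_pocket_trajectory(scfg)

  # recompute distances from the emitted coordinates (round-trip check on
  # the embedding, and the path real trajectories would take)
  defs <- embedding_defs(traj, scfg)
  distances <- compute_distances(traj$frames, defs)
  stopifnot(max(abs(as.matrix(distances[-1]) -
                    as.matrix(traj$distances[-1]))) < 1e-6)

  residue_map <- vapply(scfg$residues, `[[`, "", "distance")
  states <- classify_states(distances, residue_map,
                            in_max = config$thresholds$in_max,
                            out_min = config$thresholds$out_min)
  pca <- fit_pca(distances, variance_target = config$pca$variance_target)
  mcs <- max(2L, round(config$clustering$min_cluster_size_frac *
                       nrow(distances)))
  clustering <- cluster_density(pca$scores, min_cluster_size = mcs,
                                min_population = config$clustering$min_population)
  summary <- label_clusters(clustering, states, distances)
  reps <- sample_representatives(clustering,
                                 n_per_cluster = config$representatives,
                                 seed = seed)

  rep_frames <- unlist(reps, use.names = FALSE)
  records <- generate_electronic_records(traj$truth, scfg, frames = rep_frames)
  records$cluster <- as.character(clustering$assignment[records$snapshot])
  populations <- stats::setNames(summary$population,
                                 as.character(summary$cluster))
  stokes <- stokes_table(records, populations)

  sdens <- generate_mode_set(scfg)
  line <- cumulant_lineshape(sdens,
                             temperature = config$spectra$temperature,
                             broadening = config$spectra$broadening)
  w01 <- ev_to_cm1(records$exc_eV)
  step <- stats::median(diff(line$grid))
  abs_grid <- seq(min(w01) + min(line$grid), max(w01) + max(line$grid),
                  by = step)
  cl_ids <- as.character(summary$cluster)
  cl_spectra <- lapply(cl_ids, function(cid)
    ensemble_spectrum(records[records$cluster == cid, , drop = FALSE],
                      line, grid = abs_grid))
  names(cl_spectra) <- cl_ids
  avg <- weighted_average_spectra(cl_spectra, summary$population)
  avg_norm <- normalize_and_shift(avg, shift = config$spectra$shift)

  crowding <- NULL
  if (!is.null(v$crowding)) {
    cw <- v$crowding
    sys <- generate_crowding_frames(
      n_frames = cw$n_frames %||% 200,
      separation = cw$separation %||% 3.5,
      separation_sd = cw$separation_sd %||% 0.15,
      ring_jitter_sd = cw$ring_jitter_sd %||% 0.3,
      seed = seed)
    ov <- overlap_series(sys$frames, sys$ring_sel, sys$side_sel)
    rr <- compute_ring_rmsd(sys$frames, sys$scaffold_sel, sys$ring_sel,
                            sys$reference)
    crowding <- list(overlap = ov, ring_rmsd = rr,
                     mean_overlap = mean(ov$normalized),
                     mean_ring_rmsd = mean(rr$rmsd))
  }

  res <- list(name = v$name, states = states, pca = pca,
              clustering = clustering, summary = summary,
              representatives = reps, records = records, stokes = stokes,
              spectrum = avg_norm, cluster_spectra = cl_spectra,
              crowding = crowding, truth = traj$truth)
  if (!is.null(out_dir)) write_variant_outputs(res, distances, config, out_dir)
  res
}

# distance definitions for the generator's acceptor/donor embedding:
# roster holds atoms in (acceptor, donor) pairs, one pair per column
embedding_defs <- function(traj, scfg) {
  a <- traj$frames$atoms
  labels <- setdiff(names(traj$distances), "frame")
  k <- seq_along(labels)
  distance_defs(label = labels,
                resno_a = a$resno[2 * k - 1], elety_a = a$elety[2 * k - 1],
                resno_b = a$resno[2 * k],     elety_b = a$elety[2 * k])
}

write_variant_outputs <- function(res, distances, config, out_dir) {
  pre <- file.path(out_dir, res$name)
  tag <- function(df) { df$config_hash <- config$hash; df }
  utils::write.csv(tag(distances), paste0(pre, "_distances.csv"),
                   row.names = FALSE)
  utils::write.csv(tag(data.frame(frame = seq_along(res$clustering$assignment),
                                  cluster = res$clustering$assignment,
                                  class = res$states$class)),
                   paste0(pre, "_assignment.csv"), row.names = FALSE)
  utils::write.csv(tag(res$stokes), paste0(pre, "_stokes.csv"),
                   row.names = FALSE)
  utils::write.table(
    data.frame(wavenumber_cm1 = res$spectrum$grid,
               intensity = res$spectrum$intensity),
    paste0(pre, "_spectrum.txt"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(config_hash = config$hash,
         clusters = res$summary,
         representatives = res$representatives),
    paste0(pre, "_clusters.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(NULL)
}

report_json <- function(report) {
  list(config_hash = report$config_hash,
       variants = lapply(report$variants, function(r) list(
         name = r$name,
         clusters = r$summary,
         stokes = r$stokes,
         mean_overlap = r$crowding$mean_overlap,
         mean_ring_rmsd = r$crowding$mean_ring_rmsd)),
       delta = report$delta)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report:", length(x$variants), "variant(s)\n")
  for (r in x$variants) {
    cat(sprintf("  %s: %d cluster(s); weighted SS %.0f cm^-1\n", r$name,
                nrow(r$summary),
                r$stokes$ss_cm1[r$stokes$cluster == "avg"]))
  }
  if (!is.null(x$delta))
    cat(sprintf("  delta SS: %.1f cm^-1\n", x$delta$ss_cm1))
  invisible(x)
}
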