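# Configured, logged, reproducible pipeline binding the stages together:
# simulate -> preprocess -> netbuild -> graphmetrics -> behavior, plus the
# density sweep. Every threshold a stage applies comes from the resolved
# config, and every random draw flows from the single top-level seed
# through named substreams.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      enabled = TRUE,
      n_subjects = 8L,            # group-level sample for the edge t-test
      intra_module_corr = 0.5,
      inter_module_corr = 0.1,
      n_runs = 4L, scans_per_run = 1200L, repetition_time = 0.72,
      n_whole_brain = 128L,       # filler regions for ranking/baseline context
      ar_coef = 0.3,
      spikes_per_run = 3L, spike_size = 1.0),
    preprocess = list(
      enabled = TRUE,
      fd_threshold = 0.5,
      bandpass_low = 0.01, bandpass_high = 0.08,
      bandpass_first = TRUE),
    netbuild = list(
      density = 0.05,
      density_grid = seq(0.04, 0.10, by = 0.005),
      rule = "union",
      significance = "proportional",  # or "conjunction" with the t-test
      alpha = 0.05),
    graphmetrics = list(
      n_restarts = 10000L, n_perm = 10000L, n_rand = 10000L,
      n_restarts_null = 10L,
      q_cutoff = 0.3, z_cutoff = 3,
      null = "degree_preserving"),
    behavior = list(
      enabled = TRUE,
      n_subjects = 32L,
      coupling_rho = 0.4,
      trials_per_mixture = 15L,
      n_perm = 10000L)
  )
}

# recursively overlay user values on defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Build (and validate) a pipeline configuration
#'
#' Starts from the default configuration -- which carries the analysis
#' defaults (0.5 mm FD threshold, 0.01-0.08 Hz band, 5% connection density,
#' 4-10% density grid in 0.5% steps, Q cutoff 0.3, Z cutoff 3, 10,000
#' permutations) -- and overlays the supplied values. Unknown keys are
#' rejected.
#'
#' @param ... named top-level entries or nested lists (e.g.
#'   `netbuild = list(density = 0.10)`).
#' @param file optional YAML file merged before `...`.
#' @return a validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file))
  cfg <- merge_config(cfg, list(...))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# simulate one subject's raw timeseries + motion under the study layout
simulate_subject <- function(scenario, subject_seed) {
  spec <- ground_truth_spec(
    modules = scenario$modules,
    intra_module_corr = scenario$intra_module_corr,
    inter_module_corr = scenario$inter_module_corr,
    hub_nodes = scenario$hub_nodes,
    n_runs = scenario$n_runs, scans_per_run = scenario$scans_per_run,
    repetition_time = scenario$repetition_time,
    isolated_modules = scenario$isolated_modules,
    n_whole_brain = scenario$n_whole_brain,
    ar_coef = scenario$ar_coef,
    seed = subject_seed)
  ts <- generate_modular_timeseries(spec)
  motion <- do.call(rbind, lapply(seq_len(spec$n_runs), function(r) {
    spikes <- if (scenario$spikes_per_run > 0)
      with_seed(substream_seed(subject_seed, paste0("spikeloc", r)),
                sample(2:spec$scans_per_run, scenario$spikes_per_run))
    else integer(0)
    inject_motion(spec$scans_per_run, spike_scans = spikes,
                  spike_size = scenario$spike_size,
                  seed = substream_seed(subject_seed, paste0("motion", r)))
  }))
  list(ts = ts, motion = motion, spec = spec)
}

#' Run the full pipeline on synthetic study data
#'
#' Executes the enabled stages in order -- simulate, preprocess, network
#' construction, graph characterization, behavioral linkage -- under the
#' resolved configuration, optionally writing all artifacts (timeseries,
#' matrices, network, partition, metric tables, behavioral results, the
#' resolved config and a run manifest with checksums) under `out_dir`.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory; `NULL` skips file output.
#' @return a list of class `olfnet_pipeline` with the stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  timings <- c()
  rois <- olfactory_rois()
  scenario <- c(config$simulate,
                list(modules = rois$modules, hub_nodes = rois$hub_nodes,
                     isolated_modules = "unconnected"))
  seed <- config$seed

  # --- simulate + preprocess: one cleaned whole-context matrix per subject
  stage_t <- Sys.time()
  subject_z <- vector("list", config$simulate$n_subjects)
  baselines <- NULL
  for (s in seq_len(config$simulate$n_subjects)) {
    sub <- simulate_subject(scenario, substream_seed(seed, paste0("subj", s)))
    ts <- if (config$preprocess$enabled)
      preprocess_timeseries(sub$ts, sub$motion,
                            fd_threshold = config$preprocess$fd_threshold,
                            low = config$preprocess$bandpass_low,
                            high = config$preprocess$bandpass_high,
                            bandpass_first = config$preprocess$bandpass_first)
    else sub$ts
    z <- correlation_matrix(ts)
    subject_z[[s]] <- z
    baselines <- rbind(baselines, global_baseline(z))
  }
  timings["simulate_preprocess"] <- as.numeric(Sys.time() - stage_t, units = "secs")

  # --- netbuild: group matrix, thresholding, seeded admission
  stage_t <- Sys.time()
  group_z <- group_connectivity(subject_z)
  roi_set <- rois$roi_names
  candidates <- setdiff(roi_set, rois$key_nodes)
  adjacency <- threshold_proportional(group_z, density = config$netbuild$density,
                                      rule = config$netbuild$rule)
  ttest <- edge_ttest(lapply(subject_z, function(z) {
    zz <- unclass(z)[roi_set, roi_set]
    structure(zz, class = c("connectivity_matrix", "matrix"),
              r = attr(z, "r")[roi_set, roi_set])
  }), baselines)
  sig <- if (config$netbuild$significance == "conjunction") {
    full <- matrix(TRUE, nrow(adjacency), ncol(adjacency),
                   dimnames = dimnames(unclass_network(adjacency)))
    full[roi_set, roi_set] <- ttest$p < config$netbuild$alpha
    full
  } else NULL
  network <- build_seeded_network(adjacency, rois$key_nodes, candidates,
                                  significant = sig)
  timings["netbuild"] <- as.numeric(Sys.time() - stage_t, units = "secs")

  # --- graphmetrics on the admitted network
  stage_t <- Sys.time()
  gm <- config$graphmetrics
  partition <- modularity_louvain(network, n_restarts = gm$n_restarts,
                                  seed = substream_seed(seed, "louvain"))
  qnull <- modularity_zscore(network, n_perm = gm$n_perm, null = gm$null,
                             n_restarts_null = gm$n_restarts_null,
                             seed = substream_seed(seed, "qnull"),
                             partition = partition)
  sw_net <- largest_component(network)
  if (nrow(sw_net) < nrow(unclass_network(network)))
    warning("network is disconnected; small-world indices computed on the ",
            "largest component (", nrow(sw_net), " of ",
            nrow(unclass_network(network)), " nodes)")
  sw <- small_world(sw_net, n_rand = gm$n_rand, null = gm$null,
                    seed = substream_seed(seed, "smallworld"))
  metrics <- composite_hubness(centralities(network))
  metrics$participation <- participation_coefficient(network, partition)[metrics$node]
  metrics$deletion_impact <- node_deletion_impact(network)[metrics$node]
  timings["graphmetrics"] <- as.numeric(Sys.time() - stage_t, units = "secs")

  # --- behavior: independent cohort on the derived template
  behavior <- NULL
  if (config$behavior$enabled) {
    stage_t <- Sys.time()
    bh <- config$behavior
    net_nodes0 <- node_names(unclass_network(network))
    cohort <- generate_cohort(bh$n_subjects, network,
                              behavior_coupling_rho = bh$coupling_rho,
                              group_weights = attr(group_z, "r")[net_nodes0,
                                                                 net_nodes0],
                              trials_per_mixture = bh$trials_per_mixture,
                              seed = substream_seed(seed, "cohort"))
    masked <- lapply(cohort$subjects, function(s)
      mask_subject_network(s$connectivity, network))
    swm <- lapply(masked, weighted_small_world)
    dps <- vapply(cohort$subjects, function(s) dprime(s$trials)$dprime,
                  numeric(1))
    cw <- vapply(swm, `[[`, numeric(1), "C_w")
    gw <- vapply(swm, `[[`, numeric(1), "G_w")
    net_nodes <- node_names(unclass_network(network))
    group_r_net <- attr(group_z, "r")[net_nodes, net_nodes]
    # the validation-sample analog of the group matrix: the cohort's
    # empirical mean correlation matrix (subject noise included)
    cohort_mean_r <- Reduce(`+`, lapply(cohort$subjects,
                                        function(s) s$connectivity)) /
      length(cohort$subjects)
    behavior <- list(
      subject_table = data.frame(subject = seq_along(dps), G_w = gw,
                                 C_w = cw, dprime = dps),
      rho_clustering = spearman_perm(cw, dps, n_perm = bh$n_perm,
                                     seed = substream_seed(seed, "rho_c")),
      rho_efficiency = spearman_perm(gw, dps, n_perm = bh$n_perm,
                                     seed = substream_seed(seed, "rho_g")),
      concordance = matrix_concordance(group_r_net, cohort_mean_r,
                                       edge_set = network, n_perm = bh$n_perm,
                                       seed = substream_seed(seed, "concord")),
      cohort = cohort)
    timings["behavior"] <- as.numeric(Sys.time() - stage_t, units = "secs")
  }

  result <- structure(list(
    config = config, group_z = group_z, network = network,
    partition = partition, modularity_null = qnull, small_world = sw,
    node_metrics = metrics, edge_ttest = ttest, behavior = behavior,
    timings = timings), class = "olfnet_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
    write_matrix_csv(group_z, file.path(out_dir, "group_fisher_z.csv"))
    write_network_json(network, file.path(out_dir, "network.json"))
    write_edgelist_tsv(network, file.path(out_dir, "network_edges.tsv"))
    write_partition_json(partition, file.path(out_dir, "partition.json"))
    utils::write.csv(metrics, file.path(out_dir, "node_metrics.csv"),
                     row.names = FALSE)
    if (!is.null(behavior))
      utils::write.csv(behavior$subject_table,
                       file.path(out_dir, "behavior_subjects.csv"),
                       row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- list(
      stages = names(timings), seed = seed,
      package_version = as.character(utils::packageVersion("olfnet")),
      wall_clock_seconds = as.list(round(timings, 3)),
      checksums = as.list(tools::md5sum(files)),
      total_seconds = round(as.numeric(Sys.time() - t_start, units = "secs"), 3))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' @export
print.olfnet_pipeline <- function(x, ...) {
  cat("Olfactory network pipeline result\n")
  print(x$network)
  print(x$partition)
  cat(sprintf("  modularity Z = %.2f (cutoffs: Q > %g, Z > %g)\n",
              x$modularity_null$z, x$config$graphmetrics$q_cutoff,
              x$config$graphmetrics$z_cutoff))
  print(x$small_world)
  if (!is.null(x$behavior))
    cat(sprintf("  clustering~d' Spearman rho = %.3f (p = %.4g)\n",
                x$behavior$rho_clustering$rho, x$behavior$rho_clustering$p))
  invisible(x)
}

#' Sweep the connection density and track module structure
#'
#' For each density in the grid: threshold the group matrix, admit the
#' seeded network, partition it with Louvain, and compare the partition
#' with the reference-density partition via z-Rand over the shared nodes.
#' Emits the node x density module-assignment matrix (nodes absent from a
#' density's network are `NA`, i.e. "no longer connected").
#'
#' @param group_z group `connectivity_matrix` (ranking context).
#' @param key_nodes,candidate_nodes node sets for seeded admission.
#' @param grid densities to evaluate.
#' @param reference_density density whose partition anchors the z-Rand
#'   comparison (default 0.05).
#' @param n_restarts Louvain restarts per density.
#' @param seed integer seed.
#' @return list of class `density_sweep`: `assignment` (node x density
#'   matrix), `module_counts`, `zrand_to_reference`, `densities`.
#' @export
density_sweep <- function(group_z, key_nodes, candidate_nodes,
                          grid = seq(0.04, 0.10, by = 0.005),
                          reference_density = 0.05,
                          n_restarts = 100L, seed = 1L) {
  if (any(grid <= 0 | grid >= 1)) stop("densities must lie in (0, 1)")
  all_nodes <- c(key_nodes, candidate_nodes)
  if (!(reference_density %in% grid)) grid <- sort(c(grid, reference_density))
  parts <- list(); nets <- list()
  for (d in grid) {
    adjacency <- threshold_proportional(group_z, density = d)
    net <- build_seeded_network(adjacency, key_nodes, candidate_nodes)
    parts[[as.character(d)]] <- modularity_louvain(
      net, n_restarts = n_restarts,
      seed = substream_seed(seed, paste0("density", d)))
    nets[[as.character(d)]] <- net
  }
  assignment <- matrix(NA_integer_, length(all_nodes), length(grid),
                       dimnames = list(all_nodes, sprintf("%g", grid)))
  for (j in seq_along(grid)) {
    mem <- parts[[j]]$membership
    assignment[names(mem), j] <- mem
  }
  ref <- parts[[as.character(reference_density)]]
  zr <- vapply(seq_along(grid), function(j) {
    if (grid[j] == reference_density) return(NA_real_)
    shared <- intersect(names(parts[[j]]$membership), names(ref$membership))
    if (length(shared) < 4) return(NA_real_)
    suppressWarnings(zrand_similarity(parts[[j]]$membership[shared],
                                      ref$membership[shared]))
  }, numeric(1))
  structure(list(assignment = assignment,
                 module_counts = vapply(parts, function(p) p$n_modules,
                                        numeric(1)),
                 zrand_to_reference = stats::setNames(zr, sprintf("%g", grid)),
                 densities = grid, partitions = parts),
            class = "density_sweep")
}

#' @export
print.density_sweep <- function(x, ...) {
  cat("Density sweep:\n")
  cat("  densities:", paste(sprintf("%g", x$densities), collapse = " "), "\n")
  cat("  module counts:", paste(x$module_counts, collapse = " "), "\n")
  cat(sprintf("  mean z-rand to reference: %.2f\n",
              mean(x$zrand_to_reference, na.rm = TRUE)))
  invisible(x)
}
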