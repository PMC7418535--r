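# Synthetic inputs with planted ground truth: modular ROI timeseries,
# rigid-body motion traces, 2AFC behavioral trials, and subject cohorts.
# These emulate the statistical structure of a resting-state olfactory
# connectome study so every pipeline stage can be exercised and tested
# against known truth.

#' The 28-region olfactory ROI set used by the default ground truth
#'
#' Returns the ROI labels, the planted module composition (a sensory, a
#' limbic and a frontal subnetwork plus an unconnected remainder), the six
#' key olfactory seed regions (direct bulbar-input areas plus olfactory
#' OFC), and the two planted connector hubs (amygdala and anterior insula).
#'
#' @return a list with elements `roi_names`, `modules` (named character
#'   vector, node -> module label), `key_nodes`, `hub_nodes`.
#' @export
olfactory_rois <- function() {
  sensory <- c("APC", "PPC", "INSv", "INSd", "INSp", "THLvp")
  limbic  <- c("AMY", "OTB", "aHIP", "pHIP", "ENT", "HYP", "NAcc",
               "Opm", "Omp", "Oapc")
  frontal <- c("INSa", "Oolf", "Omm", "Oc", "Oolfl", "Opl")
  unconnected <- c("Oa", "Oal", "Oml", "THLda", "THLva", "THLdp")
  modules <- c(stats::setNames(rep("sensory", length(sensory)), sensory),
               stats::setNames(rep("limbic", length(limbic)), limbic),
               stats::setNames(rep("frontal", length(frontal)), frontal),
               stats::setNames(rep("unconnected", length(unconnected)), unconnected))
  list(roi_names = names(modules), modules = modules,
       key_nodes = c("APC", "PPC", "AMY", "ENT", "OTB", "Oolf"),
       hub_nodes = c("AMY", "INSa"))
}

#' Ground-truth specification for the modular timeseries generator
#'
#' Describes the planted correlation structure: a module label per node,
#' a within-module and a between-module correlation, designated hub nodes
#' whose cross-module correlation is elevated (by default the midpoint of
#' the intra and inter values, so hubs bridge modules without breaking the
#' planted hierarchy), and the scan layout. Module labels listed in
#' `isolated_modules` are decoupled from the rest of the graph (zero
#' between-module correlation), planting a candidate set the seeded
#' admission rule must reject. `n_whole_brain` appends uncorrelated filler
#' regions that stand in for the rest of a whole-brain parcellation, giving
#' the per-node proportional threshold and the global connectivity baseline
#' a realistic ranking context.
#'
#' @param modules named character vector mapping node name -> module label.
#' @param intra_module_corr correlation within a module, in [0, 1).
#' @param inter_module_corr correlation between modules, in [0, 1);
#'   must be smaller than `intra_module_corr`.
#' @param hub_nodes nodes with elevated cross-module correlation.
#' @param hub_corr hub cross-module correlation; default midpoint of
#'   intra and inter.
#' @param n_runs,scans_per_run scan layout (default 4 x 1200).
#' @param repetition_time TR in seconds (default 0.72).
#' @param isolated_modules module labels decoupled from all other modules.
#' @param n_whole_brain number of uncorrelated whole-brain filler regions.
#' @param ar_coef optional AR(1) coefficient in [0, 1) applied per node,
#'   giving the signals band-limited temporal structure; 0 = white noise.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return an object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(modules = olfactory_rois()$modules,
                              intra_module_corr = 0.5,
                              inter_module_corr = 0.1,
                              hub_nodes = olfactory_rois()$hub_nodes,
                              hub_corr = NULL,
                              n_runs = 4L, scans_per_run = 1200L,
                              repetition_time = 0.72,
                              isolated_modules = "unconnected",
                              n_whole_brain = 0L,
                              ar_coef = 0,
                              seed = 1L) {
  stopifnot(length(modules) >= 2, !is.null(names(modules)))
  if (anyDuplicated(names(modules))) stop("every node must have exactly one module label")
  if (!(intra_module_corr >= 0 && intra_module_corr < 1))
    stop("intra_module_corr must lie in [0, 1)")
  if (!(inter_module_corr >= 0 && inter_module_corr < 1))
    stop("inter_module_corr must lie in [0, 1)")
  if (intra_module_corr < inter_module_corr)
    stop("intra_module_corr must be at least inter_module_corr")
  if (intra_module_corr == inter_module_corr && intra_module_corr > 0)
    warning("intra_module_corr equals inter_module_corr: no modular structure is planted")
  if (!all(hub_nodes %in% names(modules)))
    stop("hub_nodes must be named in modules")
  if (is.null(hub_corr)) hub_corr <- (intra_module_corr + inter_module_corr) / 2
  if (!(hub_corr >= 0 && hub_corr < 1)) stop("hub_corr must lie in [0, 1)")
  if (ar_coef < 0 || ar_coef >= 1) stop("ar_coef must lie in [0, 1)")
  spec <- structure(list(
    n_nodes = length(modules) + n_whole_brain,
    module_assignment = modules,
    intra_module_corr = intra_module_corr,
    inter_module_corr = inter_module_corr,
    hub_nodes = hub_nodes, hub_corr = hub_corr,
    n_runs = as.integer(n_runs), scans_per_run = as.integer(scans_per_run),
    repetition_time = repetition_time,
    isolated_modules = isolated_modules,
    n_whole_brain = as.integer(n_whole_brain),
    ar_coef = ar_coef, seed = as.integer(seed)),
    class = "ground_truth_spec")
  # fail fast on an unusable correlation structure
  invisible(ground_truth_correlation(spec))
  spec
}

#' Planted node-by-node correlation matrix implied by a ground-truth spec
#'
#' @param spec a `ground_truth_spec`.
#' @return the implied correlation matrix (nodes + whole-brain fillers),
#'   checked for positive definiteness.
#' @export
ground_truth_correlation <- function(spec) {
  mods <- spec$module_assignment
  nm <- names(mods)
  p <- length(nm)
  same <- outer(mods, mods, "==")
  R <- matrix(spec$inter_module_corr, p, p, dimnames = list(nm, nm))
  R[same] <- spec$intra_module_corr
  iso <- names(mods)[mods %in% spec$isolated_modules]
  if (length(iso)) {
    R[iso, setdiff(nm, iso)] <- 0
    R[setdiff(nm, iso), iso] <- 0
    R[iso, iso] <- spec$intra_module_corr
  }
  for (h in spec$hub_nodes) {
    cross <- nm[mods != mods[h] & !(nm %in% iso)]
    if (h %in% iso) cross <- character(0)
    R[h, cross] <- spec$hub_corr
    R[cross, h] <- spec$hub_corr
  }
  diag(R) <- 1
  if (spec$n_whole_brain > 0) {
    # whole-brain fillers share the global baseline correlation level
    # (the between-module value), mimicking the diffuse low-level coupling
    # of real whole-brain parcels; decoupled modules stay decoupled
    wb <- sprintf("WB%03d", seq_len(spec$n_whole_brain))
    full <- matrix(spec$inter_module_corr, p + spec$n_whole_brain,
                   p + spec$n_whole_brain,
                   dimnames = list(c(nm, wb), c(nm, wb)))
    full[nm, nm] <- R
    if (length(iso)) { full[iso, wb] <- 0; full[wb, iso] <- 0 }
    diag(full) <- 1
    R <- full
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    stop(sprintf(paste0("implied correlation matrix is not positive definite ",
                        "(min eigenvalue %.3g); intra=%.3g, inter=%.3g, ",
                        "hub_corr=%.3g are jointly infeasible"),
                 ev, spec$intra_module_corr, spec$inter_module_corr,
                 spec$hub_corr))
  R
}

#' Generate multi-run ROI timeseries with a planted modular correlation
#'
#' Draws zero-mean unit-variance Gaussian signals whose correlation matrix
#' is the one implied by `spec` (within-module `intra_module_corr`,
#' between-module `inter_module_corr`, elevated hub cross-correlation).
#' With `ar_coef > 0` an AR(1) filter is applied per node after mixing,
#' which leaves the cross-node correlation untouched while concentrating
#' power at low frequencies. Output is bit-identical for identical specs.
#'
#' @param spec a `ground_truth_spec`.
#' @return a [roi_timeseries] of `n_runs * scans_per_run` scans.
#' @export
generate_modular_timeseries <- function(spec) {
  R <- ground_truth_correlation(spec)
  p <- ncol(R)
  L <- chol(R)
  n <- spec$scans_per_run
  phi <- spec$ar_coef
  with_seed(spec$seed, {
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      x <- matrix(stats::rnorm(n * p), n, p) %*% L
      if (phi > 0) {
        # AR(1) per node (vectorized over nodes); innovations rescaled to
        # keep unit marginal variance, cross-node correlation is untouched
        x <- x * sqrt(1 - phi^2)
        for (t in 2:n) x[t, ] <- x[t, ] + phi * x[t - 1, ]
      }
      x
    })
    values <- do.call(rbind, runs)
  })
  colnames(values) <- colnames(R)
  roi_timeseries(values, tr = spec$repetition_time,
                 run = rep(seq_len(spec$n_runs), each = n))
}

#' Synthesize a rigid-body motion trace with injected displacement spikes
#'
#' Produces a smooth, low-amplitude six-parameter trace (three translations
#' in mm, three rotations pre-converted to mm equivalents) and adds a step
#' displacement of `spike_size` mm at each listed scan, so the framewise
#' displacement at those scans is guaranteed to reach at least `spike_size`.
#'
#' @param n_scans number of scans in the run.
#' @param spike_scans integer scan indices (>= 2) receiving a spike.
#' @param spike_size displacement jump in mm.
#' @param baseline_sd standard deviation of the smooth baseline (mm);
#'   0 gives a perfectly still trace.
#' @param seed integer seed.
#' @return an `n_scans` x 6 matrix (class `motion_trace`) with columns
#'   `trans_x/y/z`, `rot_x/y/z`.
#' @export
inject_motion <- function(n_scans, spike_scans = integer(0), spike_size = 1,
                          baseline_sd = 0.02, seed = 1L) {
  spike_scans <- as.integer(spike_scans)
  if (length(spike_scans) &&
      (min(spike_scans) < 2 || max(spike_scans) > n_scans))
    stop("spike_scans must lie in [2, n_scans]")
  m <- with_seed(seed, {
    if (baseline_sd > 0) {
      raw <- matrix(stats::rnorm(n_scans * 6), n_scans, 6)
      # heavy AR smoothing gives slow, drift-like motion
      sm <- apply(raw, 2, function(col)
        as.numeric(stats::filter(col, 0.98, method = "recursive")))
      sweep(sm, 2, apply(sm, 2, stats::sd) / baseline_sd, "/")
    } else matrix(0, n_scans, 6)
  })
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  for (s in spike_scans) {
    # step change aligned with the baseline's own delta so the framewise
    # displacement at scan s is |baseline delta| + spike_size
    delta <- m[s, "trans_x"] - m[s - 1, "trans_x"]
    sgn <- if (delta >= 0) 1 else -1
    m[s:n_scans, "trans_x"] <- m[s:n_scans, "trans_x"] + sgn * spike_size
  }
  class(m) <- c("motion_trace", class(m))
  m
}

#' Simulate 2AFC odor-discrimination trials from a Gaussian observer
#'
#' Five binary mixtures (80/20, 60/40, 50/50, 40/60, 20/80 ratios of the
#' A odorant) are each presented `trials_per_mixture` times. Responses to
#' the extreme mixtures are drawn from an equal-variance Gaussian observer
#' with sensitivity `true_dprime`; intermediate mixtures use a sensitivity
#' scaled linearly in the dominant-component proportion (a generator
#' convention, documented here, that makes the middle mixtures harder
#' without affecting the extreme-mixture d-prime).
#'
#' @param true_dprime observer sensitivity for the extreme mixtures.
#' @param trials_per_mixture trials per mixture (default 15).
#' @param seed integer seed.
#' @return a data frame with columns `mixture`, `truth` (dominant odor,
#'   `A`/`B`), and `response` (`A`/`B`).
#' @export
generate_2afc_trials <- function(true_dprime, trials_per_mixture = 15L,
                                 seed = 1L) {
  if (trials_per_mixture < 1) stop("trials_per_mixture must be >= 1")
  mixtures <- c("80/20", "60/40", "50/50", "40/60", "20/80")
  prop_a <- c(0.8, 0.6, 0.5, 0.4, 0.2)
  with_seed(seed, {
    rows <- lapply(seq_along(mixtures), function(i) {
      # signed sensitivity, linear in dominant-component proportion
      d <- true_dprime * (prop_a[i] - 0.5) / 0.3
      p_respond_a <- stats::pnorm(d / 2)
      resp <- ifelse(stats::runif(trials_per_mixture) < p_respond_a, "A", "B")
      truth <- if (prop_a[i] > 0.5) "A" else if (prop_a[i] < 0.5) "B" else
        sample(c("A", "B"), trials_per_mixture, replace = TRUE)
      data.frame(mixture = mixtures[i], truth = truth, response = resp,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[sample.int(nrow(out)), , drop = FALSE]  # intermix trial order
  })
  rownames(out) <- NULL
  out
}

#' Generate a cohort of subject networks with planted behavioral coupling
#'
#' Each subject receives a correlation matrix consistent with a shared
#' group binary topology (template edges carry strong weights, non-edges
#' weak ones) plus subject-specific Gaussian noise, and a set of 2AFC
#' trials. Subjects' true sensitivities are generated through a Gaussian
#' copula on the rank of their weighted clustering coefficient, so the
#' population Spearman correlation between weighted clustering and true
#' d-prime equals `behavior_coupling_rho`.
#'
#' @param n_subjects number of subjects.
#' @param template a `binary_network` (see [threshold_proportional]).
#' @param behavior_coupling_rho target Spearman correlation in [-1, 1].
#' @param group_weights optional matrix of group-level correlations the
#'   cohort is centred on (e.g. a source sample's mean correlation
#'   matrix); when `NULL`, edge/non-edge weights are drawn from the ranges
#'   below.
#' @param edge_weight_range range of group-level edge correlations.
#' @param nonedge_weight_range range of group-level non-edge correlations.
#' @param noise_sd subject-level correlation noise SD.
#' @param dprime_mean,dprime_sd population distribution of true d-prime.
#' @param trials_per_mixture 2AFC trials per mixture per subject.
#' @param seed integer seed.
#' @return a list of class `synthetic_cohort`: `subjects` (each with
#'   `connectivity` (correlation matrix), `trials`, `true_dprime`),
#'   `template`, and `group_r` (the noise-free group correlation matrix).
#' @export
generate_cohort <- function(n_subjects, template, behavior_coupling_rho = 0,
                            group_weights = NULL,
                            edge_weight_range = c(0.35, 0.6),
                            nonedge_weight_range = c(0.0, 0.15),
                            noise_sd = 0.08,
                            dprime_mean = 1.5, dprime_sd = 0.5,
                            trials_per_mixture = 15L, seed = 1L) {
  A <- unclass_network(template)
  if (sum(A) == 0) stop("degenerate template: no edges")
  if (abs(behavior_coupling_rho) > 1) stop("|behavior_coupling_rho| must be <= 1")
  nm <- node_names(A)
  p <- length(nm)
  ut <- upper.tri(A)
  with_seed(seed, {
    if (is.null(group_weights)) {
      group_r <- matrix(0, p, p, dimnames = list(nm, nm))
      w <- ifelse(A[ut] == 1,
                  stats::runif(sum(ut), edge_weight_range[1], edge_weight_range[2]),
                  stats::runif(sum(ut), nonedge_weight_range[1], nonedge_weight_range[2]))
      group_r[ut] <- w
      group_r <- group_r + t(group_r)
      diag(group_r) <- 1
    } else {
      if (!all(nm %in% node_names(group_weights)))
        stop("group_weights must cover the template nodes")
      group_r <- as.matrix(group_weights)[nm, nm]
      diag(group_r) <- 1
    }
    subjects <- lapply(seq_len(n_subjects), function(s) {
      noise <- matrix(0, p, p)
      noise[ut] <- stats::rnorm(sum(ut), 0, noise_sd)
      r <- group_r + noise + t(noise)
      r[r > 0.999] <- 0.999; r[r < -0.999] <- -0.999
      diag(r) <- 1
      dimnames(r) <- list(nm, nm)
      list(connectivity = r)
    })
    # clustering rank -> true d-prime through a Gaussian copula; the
    # Pearson correlation on the latent scale is chosen so the implied
    # population Spearman equals the requested coupling
    cw <- vapply(subjects, function(s)
      weighted_small_world(mask_subject_network(s$connectivity, template))$C_w,
      numeric(1))
    z_c <- stats::qnorm((rank(cw, ties.method = "average") - 0.5) / n_subjects)
    r_lat <- 2 * sin(pi * behavior_coupling_rho / 6)
    z_d <- r_lat * z_c + sqrt(1 - r_lat^2) * stats::rnorm(n_subjects)
    true_d <- dprime_mean + dprime_sd * z_d
    trial_seeds <- sample.int(2^31 - 2, n_subjects)
    for (s in seq_len(n_subjects)) {
      subjects[[s]]$true_dprime <- true_d[s]
      subjects[[s]]$trials <- generate_2afc_trials(true_d[s],
                                                   trials_per_mixture,
                                                   seed = trial_seeds[s])
    }
  })
  structure(list(subjects = subjects, template = template, group_r = group_r),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d-node template\n",
              length(x$subjects), ncol(x$group_r)))
  invisible(x)
}
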