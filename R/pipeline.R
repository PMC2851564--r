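## Orchestration of the three analyses (intrinsic dynamics, communication,
## family comparison) from a single config list, mirroring how the study
## conditions are run end-to-end. Configs are plain named lists; a YAML file
## path is accepted wherever a config is expected.

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

as_model <- function(x, include_ligands = FALSE, chains = NULL) {
  if (inherits(x, "coarse_model")) return(x)
  if (is.character(x) && length(x) == 1) {
    return(build_coarse_model(read_structure(x),
                              include_ligands = include_ligands,
                              chains = chains))
  }
  stopf("expected a coarse_model or a PDB path")
}

as_mapping <- function(x, n_a = NULL, n_b = NULL) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "alignment_map")) return(x)
  read_alignment_map(x, n_a = n_a, n_b = n_b)
}

write_manifest <- function(out_dir, stage, params) {
  manifest <- list(
    stage = stage,
    package = "aakdyn",
    version = as.character(utils::packageVersion("aakdyn")),
    parameters = params)
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Intrinsic dynamics report (GNM/ANM, B-factors, hinges, overlaps)
#'
#' Runs the mobility analysis of a structure: GNM mean-square fluctuations
#' and B-factor comparison, per-mode mobility profiles and hinge sites for
#' the slowest GNM modes, the GNM-to-ANM mode correspondence, and -- when a
#' second ("closed") conformation is configured -- per-mode and cumulative
#' overlaps of the ANM modes with the open-to-closed deformation, plus
#' conformer generation along requested modes.
#'
#' @param config Named list (or YAML path) with fields: \code{open} (PDB
#'   path or \code{coarse_model}), optional \code{closed}, optional
#'   \code{mapping} (pair-list path or \code{\link{alignment_map}}),
#'   \code{gnm_cutoff} (10), \code{anm_cutoff} (15), \code{n_slow_modes}
#'   (3), \code{n_overlap_modes} (50), \code{conformer_modes} (integer
#'   vector, default none), \code{conformer_rmsd} (1), \code{chains},
#'   \code{include_ligands} (FALSE), \code{out_dir} (optional; CSV tables
#'   and a JSON run manifest are written there).
#' @return Report list with elements \code{msf_table}, \code{bfactor_r},
#'   \code{mode_mobility}, \code{hinges}, \code{gnm_anm_map},
#'   \code{overlap_table} (NULL when no closed form), \code{gnm},
#'   \code{anm}, \code{model}, and \code{notices}.
#' @export
run_intrinsic_dynamics <- function(config) {
  cfg <- load_config(config)
  gnm_cutoff <- cfg$gnm_cutoff %||% 10
  anm_cutoff <- cfg$anm_cutoff %||% 15
  n_slow <- cfg$n_slow_modes %||% 3
  notices <- character(0)

  model <- as_model(cfg$open, isTRUE(cfg$include_ligands), cfg$chains)
  gnm <- decompose_modes(build_kirchhoff(model, cutoff = gnm_cutoff))
  anm <- decompose_modes(build_hessian(model, cutoff = anm_cutoff))

  msf <- msf_profile(gnm)
  bf <- if (sum(is.finite(model$b)) >= 3 &&
            stats::sd(model$b[is.finite(model$b)]) > 0) {
    predict_bfactors(msf, model$b)
  } else {
    notices <- c(notices, "B-factor comparison skipped: no usable experimental values")
    list(predicted = rep(NA_real_, model$N), r = NA_real_)
  }
  msf_table <- data.frame(label = model$label, msf = msf,
                          b_exp = model$b, b_pred = bf$predicted)

  mode_mobility <- sapply(seq_len(n_slow), function(k) msf_profile(gnm, k))
  colnames(mode_mobility) <- paste0("mode", seq_len(n_slow))
  hinges <- lapply(seq_len(n_slow), function(k) {
    idx <- find_hinges(mode_vector(gnm, k), chain = model$chain)
    list(mode = k, index = idx, label = model$label[idx])
  })
  gnm_anm <- map_gnm_to_anm(gnm, anm, n_modes_map = min(n_slow, 3))

  overlap_table <- NULL
  deform <- NULL
  if (!is.null(cfg$closed)) {
    closed <- as_model(cfg$closed, isTRUE(cfg$include_ligands), cfg$chains)
    mapping <- as_mapping(cfg$mapping, model$N, closed$N)
    deform <- deformation_vector(model, closed, mapping)
    m_max <- min(cfg$n_overlap_modes %||% 50, n_modes(anm))
    overlap_table <- overlap_profile(anm, deform, m_max)
  } else {
    notices <- c(notices, "no closed structure configured: overlap analysis skipped")
  }

  conformers <- NULL
  if (length(cfg$conformer_modes %||% integer(0)) > 0) {
    conformers <- lapply(cfg$conformer_modes, function(k) {
      generate_conformers(model, anm, k, rmsd = cfg$conformer_rmsd %||% 1)
    })
    names(conformers) <- paste0("mode", cfg$conformer_modes)
  }

  report <- list(msf_table = msf_table, bfactor_r = bf$r,
                 mode_mobility = mode_mobility, hinges = hinges,
                 gnm_anm_map = gnm_anm, overlap_table = overlap_table,
                 deformation = deform, conformers = conformers,
                 gnm = gnm, anm = anm, model = model, notices = notices)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(msf_table, file.path(cfg$out_dir, "msf_bfactors.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(label = model$label, as.data.frame(mode_mobility)),
                     file.path(cfg$out_dir, "mode_mobility.csv"),
                     row.names = FALSE)
    if (!is.null(overlap_table)) {
      utils::write.csv(overlap_table, file.path(cfg$out_dir, "overlaps.csv"),
                       row.names = FALSE)
    }
    for (nm in names(conformers %||% list())) {
      write_coarse_pdb(model, file.path(cfg$out_dir, paste0("conformer_", nm, "_plus.pdb")),
                       coords = conformers[[nm]]$plus)
      write_coarse_pdb(model, file.path(cfg$out_dir, paste0("conformer_", nm, "_minus.pdb")),
                       coords = conformers[[nm]]$minus)
    }
    write_manifest(cfg$out_dir, "intrinsic",
                   list(gnm_cutoff = gnm_cutoff, anm_cutoff = anm_cutoff,
                        n_slow_modes = n_slow,
                        bfactor_r = bf$r))
  }
  report
}

#' Communication report (hitting times, profiles, pathways)
#'
#' For each configured state, builds the heavy-atom contact affinity model
#' and its Markov chain, computes analytic hitting/commute times, the mean
#' hitting-time profile, mean/SD hitting times between configured node
#' groups, and requested optimal pathways. With two or more states, the
#' cross-correlation contribution difference map between the first and last
#' state is included.
#'
#' @param config Named list (or YAML path) with fields: \code{states}
#'   (named list; each element a PDB path/\code{coarse_model} or a list
#'   with \code{model} and \code{include_ligands}), \code{threshold} (4),
#'   \code{groups} (named list of node index vectors), \code{paths} (list
#'   of length-2 vectors of node indices or labels),
#'   \code{profile_convention} ("receiver"), \code{out_dir} (optional).
#' @return Report list with \code{states} (per-state: \code{comm},
#'   \code{profile}, \code{group_stats}, \code{paths}),
#'   \code{difference_map}, \code{notices}.
#' @export
run_communication <- function(config) {
  cfg <- load_config(config)
  threshold <- cfg$threshold %||% 4
  convention <- cfg$profile_convention %||% "receiver"
  if (is.null(cfg$states) || length(cfg$states) == 0) {
    stopf("config must define at least one state")
  }
  notices <- character(0)

  states <- lapply(cfg$states, function(st) {
    if (is.list(st) && !inherits(st, "coarse_model")) {
      model <- as_model(st$model, isTRUE(st$include_ligands), st$chains)
    } else {
      model <- as_model(st)
    }
    aff <- build_affinity(model, threshold = threshold)
    comm <- hitting_times(aff)
    markov <- build_markov(aff)
    profile <- mean_receive_time(comm, convention)
    group_stats <- NULL
    if (length(cfg$groups %||% list()) >= 2) {
      gn <- names(cfg$groups)
      pairs <- utils::combn(gn, 2, simplify = FALSE)
      group_stats <- do.call(rbind, lapply(pairs, function(p) {
        gs <- group_path_stats(comm, cfg$groups[[p[1]]], cfg$groups[[p[2]]])
        data.frame(group_a = p[1], group_b = p[2],
                   mean = gs$mean, sd = gs$sd, n_pairs = gs$n_pairs)
      }))
    }
    paths <- lapply(cfg$paths %||% list(), function(p) {
      shortest_path(markov, p[[1]], p[[2]])
    })
    list(model = model, affinity = aff, comm = comm, markov = markov,
         profile = profile, group_stats = group_stats, paths = paths)
  })

  difference_map <- NULL
  if (length(states) >= 2) {
    first <- states[[1]]$comm
    last <- states[[length(states)]]$comm
    mapping <- as_mapping(cfg$state_mapping,
                          length(first$d), length(last$d))
    if (is.null(mapping) && length(first$d) != length(last$d)) {
      notices <- c(notices,
                   "difference map skipped: states differ in size and no state_mapping given")
    } else {
      difference_map <- decompose_hitting(first, last, mapping)$difference
    }
  }

  report <- list(states = states, difference_map = difference_map,
                 convention = convention, notices = notices)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(states)) {
      st <- states[[nm]]
      utils::write.csv(data.frame(label = st$model$label, mean_hitting = st$profile),
                       file.path(cfg$out_dir, paste0("profile_", nm, ".csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(st$comm$H),
                       file.path(cfg$out_dir, paste0("hitting_", nm, ".csv")),
                       row.names = FALSE)
      if (!is.null(st$group_stats)) {
        utils::write.csv(st$group_stats,
                         file.path(cfg$out_dir, paste0("group_stats_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
    write_manifest(cfg$out_dir, "communication",
                   list(threshold = threshold, convention = convention,
                        states = names(states)))
  }
  report
}

#' Family slow-mode conservation report
#'
#' Compares the slow ANM modes of a reference structure with those of
#' another family member over their structurally aligned positions: the
#' aligned nodes form the subsystem, the unaligned remainder the coupling
#' environment, and modes come from the effective (Schur-complement)
#' Hessian of each subsystem. The other structure is rigidly superposed
#' onto the reference over the aligned C-alphas before directions are
#' compared.
#'
#' @param config Named list (or YAML path) with fields: \code{ref},
#'   \code{other} (PDB paths or \code{coarse_model}s), \code{mapping}
#'   (required unless the models are same-size, then defaults to identity),
#'   \code{anm_cutoff} (15), \code{n_modes} (10), \code{out_dir} (optional).
#' @return Report list with \code{correlation} (n x n absolute cosines),
#'   \code{summary_percent} (mean CO over the first n modes, as a
#'   percentage), \code{modes_ref}, \code{modes_other}.
#' @export
run_family_comparison <- function(config) {
  cfg <- load_config(config)
  anm_cutoff <- cfg$anm_cutoff %||% 15
  nm <- cfg$n_modes %||% 10

  ref <- as_model(cfg$ref)
  other <- as_model(cfg$other)
  mapping <- as_mapping(cfg$mapping, ref$N, other$N)
  if (is.null(mapping)) {
    if (ref$N != other$N) stopf("models differ in size; a mapping is required")
    mapping <- alignment_map(seq_len(ref$N), seq_len(other$N))
  }

  ## compare directions in the reference frame
  fit <- superpose(ref, other, mapping)
  other_fit <- other
  other_fit$xyz <- fit$b_fitted

  sub_modes <- function(model, nodes) {
    hess <- build_hessian(model, cutoff = anm_cutoff)
    if (length(nodes) == model$N) return(decompose_modes(hess))
    subsystem_modes(effective_hessian(hess, nodes))
  }
  s_ref <- sort(unique(mapping[, "a"]))
  s_other <- sort(unique(mapping[, "b"]))
  modes_ref <- sub_modes(ref, s_ref)
  modes_other <- sub_modes(other_fit, s_other)

  ## mapping in subsystem-local index space (effective Hessians keep sorted
  ## node order)
  local_map <- alignment_map(match(mapping[, "a"], s_ref),
                             match(mapping[, "b"], s_other))
  cmat <- mode_correlation_matrix(modes_ref, modes_other, local_map, n = nm)
  summary_percent <- family_overlap_summary(cmat, m = nm)

  report <- list(correlation = cmat, summary_percent = summary_percent,
                 modes_ref = modes_ref, modes_other = modes_other,
                 mapping = mapping)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(cmat),
                     file.path(cfg$out_dir, "mode_correlations.csv"),
                     row.names = FALSE)
    write_manifest(cfg$out_dir, "family",
                   list(anm_cutoff = anm_cutoff, n_modes = nm,
                        summary_percent = summary_percent))
  }
  report
}
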