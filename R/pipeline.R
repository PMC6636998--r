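#' Read a pipeline configuration file (JSON or YAML)
#'
#' The configuration names the input trajectories per liganded state and the
#' analysis parameters. Recognised keys (defaults in parentheses):
#' `states` (named list: state -> vector of trajectory paths, or
#' `list(coords, topology)` pairs for table input), `library` (bundled
#' default), `n_blocks` (20), `omega_threshold` (0.85), `min_run` (2),
#' `pseudocount` (1e-3), `lfc_min` (2), `q_max` (5e-4), `p_max` (NULL),
#' `cutoff` (0.75), `min_nmi` (0.01), `sources`, `sinks` (residue index
#' vectors), `reference` (path; default: first trajectory of the first
#' state), `temperature` (300), `seed` (1), `out_dir`.
#'
#' @param path Config file (`.json`, `.yml`, `.yaml`).
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  pipeline_config(cfg)
}

#' Validate and complete a pipeline configuration
#' @param cfg Named list of configuration values (see
#'   [read_pipeline_config()]).
#' @return The completed list, classed `pipeline_config`.
#' @export
pipeline_config <- function(cfg = list()) {
  defaults <- list(
    library = NULL, n_blocks = 20L, omega_threshold = 0.85, min_run = 2L,
    pseudocount = 1e-3, lfc_min = 2, q_max = 5e-4, p_max = NULL,
    cutoff = 0.75, min_nmi = 0.01, sources = NULL, sinks = NULL,
    reference = NULL, temperature = 300, seed = 1L, out_dir = NULL,
    mask_overlap = TRUE
  )
  out <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, logical(1))])
  if (!is.null(out$states)) {
    if (length(out$states) != 2L || is.null(names(out$states))) {
      abort("`states` must be a named list of exactly two liganded states.")
    }
  }
  with(out, {
    stopifnot(n_blocks >= 1L, omega_threshold > 0, omega_threshold <= 1,
              min_run >= 1L, pseudocount >= 0, lfc_min >= 0,
              q_max > 0, q_max <= 1, cutoff > 0, min_nmi >= 0,
              temperature > 0)
  })
  class(out) <- "pipeline_config"
  out
}

#' Write a pipeline configuration to JSON (lossless round-trip)
#' @param cfg A [pipeline_config()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.read_any_traj <- function(entry) {
  if (is.character(entry) && length(entry) == 1L) {
    return(read_pdb_multimodel(entry))
  }
  if (is.list(entry) && !is.null(entry$coords) && !is.null(entry$topology)) {
    return(read_table_traj(entry$coords, entry$topology))
  }
  abort("Each trajectory entry must be a PDB path or list(coords, topology).")
}

#' Run the full hub-detection pipeline
#'
#' Encodes every replica trajectory of both liganded states with the
#' structural alphabet, computes per-chain block nMI matrices, segments each
#' (replica, chain) series into conformational substates, builds
#' probability-weighted ensemble networks per state, contrasts them
#' (difference network, rank-sum + BH), ranks hub fragments, and — when
#' source/sink residues are configured — traces minimal communication
#' pathways over the contact-gated coupling graph of the reference
#' structure. Deterministic given (inputs, config, seed).
#'
#' @param config A [pipeline_config()] (or named list coerced by it) with a
#'   `states` entry naming two states; the first is treated as the
#'   reference/apo state, the second as the perturbed/holo state.
#' @return List of class `pipeline_result`: `hubs` (a `hub_table`),
#'   `diff` (a `diff_network`), `ensembles`, `substates` (nested per
#'   state/replica/chain), `paths` (or `NULL`), `path_overlap`,
#'   `provenance`. When `config$out_dir` is set, writes `hubs.csv`,
#'   `hub_pairs.csv`, `substates.json`, `paths.json`, `provenance.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(config$states)) abort("Config must define `states`.")
  library <- if (is.null(config$library)) default_library()
             else load_library(config$library)
  state_names <- names(config$states)
  message(sprintf("[allohub] states: %s vs %s",
                  state_names[1], state_names[2]))
  substate_log <- list()
  sets_by_state <- list()
  first_traj <- NULL
  for (st in state_names) {
    entries <- config$states[[st]]
    if (is.character(entries)) entries <- as.list(entries)
    sets <- list()
    for (r in seq_along(entries)) {
      traj <- .read_any_traj(entries[[r]])
      if (is.null(first_traj)) first_traj <- traj
      aln <- encode_trajectory(traj, library)
      blocks <- split_blocks(aln, config$n_blocks)
      for (ch in unique(aln$fragments$chain)) {
        mats <- lapply(seq_len(nrow(blocks)), function(b) {
          block_mi_matrix(aln, frames = blocks$start[b]:blocks$end[b],
                          chain = ch, mask_overlap = config$mask_overlap,
                          provenance = list(state = st, replica = r,
                                            block = b))
        })
        ss <- segment_substates(mats, config$omega_threshold, config$min_run)
        sets[[length(sets) + 1L]] <- ss
        substate_log[[length(substate_log) + 1L]] <- c(
          list(state = st, replica = r, chain = ch),
          as.list(glance(ss)[c("n_substates", "n_blocks")]),
          list(substates = tidy(ss)))
      }
      message(sprintf("[allohub]   %s replica %d: %d frames encoded",
                      st, r, n_frames(traj)))
    }
    sets_by_state[[st]] <- sets
  }
  ens_apo <- ensemble_average(sets_by_state[[1]], state = state_names[1])
  ens_holo <- ensemble_average(sets_by_state[[2]], state = state_names[2])
  diff <- difference_network(ens_apo, ens_holo,
                             pseudocount = config$pseudocount)
  hubs <- call_hubs(diff, lfc_min = config$lfc_min, q_max = config$q_max,
                    p_max = config$p_max)
  paths <- NULL; overlap <- NULL
  if (!is.null(config$sources) && !is.null(config$sinks)) {
    reference <- if (is.null(config$reference)) first_traj
                 else .read_any_traj(config$reference)
    graph <- build_graph(ens_holo, reference, cutoff = config$cutoff,
                         min_nmi = config$min_nmi)
    src <- fragments_for_residues(graph, config$sources)
    snk <- fragments_for_residues(graph, config$sinks)
    if (length(src) && length(snk)) {
      paths <- shortest_path(graph, src, snk, k = max(length(snk), 1L))
      overlap <- hub_path_overlap(paths, hubs)
    }
  }
  provenance <- list(
    package = "allohubr",
    version = as.character(utils::packageVersion("allohubr")),
    library = library$name,
    parameters = unclass(config)[c("n_blocks", "omega_threshold", "min_run",
                                   "pseudocount", "lfc_min", "q_max",
                                   "p_max", "cutoff", "min_nmi", "seed")],
    states = lapply(config$states, function(e)
      if (is.character(e)) e else "table-input"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  result <- structure(
    list(hubs = hubs, diff = diff,
         ensembles = list(apo = ens_apo, holo = ens_holo),
         substates = substate_log, paths = paths, path_overlap = overlap,
         provenance = provenance),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$hubs)
  invisible(x)
}

#' Write pipeline outputs to a directory
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$hubs$hubs, file.path(out_dir, "hubs.csv"),
            row.names = FALSE)
  write.csv(dplyr::select(result$hubs$pairs, -"i", -"j"),
            file.path(out_dir, "hub_pairs.csv"), row.names = FALSE)
  ss <- lapply(result$substates, function(s) {
    s$substates <- as.data.frame(s$substates)
    s
  })
  jsonlite::write_json(ss, file.path(out_dir, "substates.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$paths)) {
    pj <- lapply(seq_len(nrow(result$paths)), function(r) {
      list(sink = result$paths$sink[r],
           path = result$paths$path[[r]],
           cost = result$paths$cost[r],
           reachable = result$paths$reachable[r])
    })
    jsonlite::write_json(list(paths = pj,
                              hub_on_path = result$path_overlap$fraction),
                         file.path(out_dir, "paths.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
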