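#' Trajectory container
#'
#' Holds a Cartesian coordinate trajectory (frames x atoms x 3, in nm) with a
#' per-atom topology and per-frame times. All analysis in the package starts
#' from this container; binary MD formats are expected to be converted
#' upstream (e.g. to multi-model PDB or a plain coordinate table).
#'
#' @param coords Numeric array `frames x atoms x 3` (nm).
#' @param topology Data frame with one row per atom and columns
#'   `chain` (chain id), `resid` (1-based residue index), `resname`,
#'   `name` (atom name, Calpha atoms are `"CA"`), `mass` (Da, > 0).
#' @param times Optional per-frame times (ns), strictly increasing; defaults
#'   to `0, 1, 2, ...` frame units.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(coords, topology, times = NULL) {
  coords <- unclass(coords)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("`coords` must be a frames x atoms x 3 array.")
  }
  topology <- as_tibble(topology)
  need <- c("chain", "resid", "resname", "name", "mass")
  miss <- setdiff(need, names(topology))
  if (length(miss)) {
    abort(paste0("Topology is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (nrow(topology) != dim(coords)[2]) {
    abort(sprintf("Topology has %d atoms but coords have %d.",
                  nrow(topology), dim(coords)[2]))
  }
  if (any(!is.finite(topology$mass)) || any(topology$mass <= 0)) {
    abort("All atom masses must be positive and finite.")
  }
  n_frames <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(n_frames) - 1L)
  if (length(times) != n_frames || any(diff(times) <= 0)) {
    abort("`times` must have one strictly increasing value per frame.")
  }
  structure(
    list(coords = coords, topology = topology, times = as.numeric(times)),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<Trajectory> %d frames x %d atoms, %d chain(s), t = [%g, %g]\n",
              d[1], d[2], length(unique(x$topology$chain)),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.Trajectory <- function(x) dim(x$coords)

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract the coordinates of one frame
#' @param traj A [trajectory()].
#' @param frame Frame index (1-based).
#' @return Numeric atoms x 3 matrix (nm).
#' @export
frame_coords <- function(traj, frame = 1L) {
  stopifnot(frame >= 1L, frame <= n_frames(traj))
  matrix(traj$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select Calpha chains suitable for fragment encoding
#'
#' Returns one row per chain with the ordered Calpha atom indices and residue
#' indices. Chains with fewer than 4 Calpha residues cannot host a 4-residue
#' fragment and are excluded with a warning.
#'
#' @param traj A [trajectory()].
#' @return A tibble with columns `chain`, `n_res`, and list-columns
#'   `atom_idx`, `resid`.
#' @export
select_calpha <- function(traj) {
  top <- traj$topology
  is_ca <- top$name == "CA"
  if (!any(is_ca)) abort("No Calpha (atom name 'CA') atoms in topology.")
  ca <- dplyr::mutate(top[is_ca, ], atom = which(is_ca))
  out <- ca |>
    dplyr::group_by(.data$chain) |>
    dplyr::arrange(.data$resid, .by_group = TRUE) |>
    dplyr::summarise(
      n_res = dplyr::n(),
      atom_idx = list(.data$atom),
      resid = list(.data$resid),
      .groups = "drop"
    )
  bad_order <- vapply(out$resid, function(r) any(diff(r) <= 0), logical(1))
  if (any(bad_order)) {
    abort(paste0("Duplicated or non-increasing residue indices in chain(s): ",
                 paste(out$chain[bad_order], collapse = ", ")))
  }
  short <- out$n_res < 4L
  if (any(short)) {
    warn(paste0("Excluding chain(s) with < 4 residues (not encodable): ",
                paste(out$chain[short], collapse = ", ")))
    out <- out[!short, ]
  }
  if (nrow(out) == 0L) abort("No encodable chains (>= 4 Calpha residues).")
  out
}
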