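## Trajectory, alignment and table I/O.
##
## Only plain-text formats are handled here: multi-model PDB, a delimited
## coordinate table with a topology sidecar, and FASTA for encoded
## alignments. Binary MD formats (XTC/DCD) are out of scope; supply an
## adapter that yields frames (see `read_table_traj`) after converting
## upstream.

.element_mass <- function(element) {
  element <- toupper(trimws(element))
  m <- .atomic_weights[element]
  if (any(is.na(m))) {
    abort(paste0("Unknown element(s): ",
                 paste(unique(element[is.na(m)]), collapse = ", "),
                 ". Provide masses explicitly."))
  }
  unname(m)
}

.guess_element <- function(name) {
  # PDB atom-name convention: element is right-justified in cols 13-14;
  # fall back to the first alphabetic character of the stripped name.
  nm <- trimws(name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% names(.atomic_weights) & nchar(nm) >= 2 &
           !grepl("^[CHNOSP][A-Z0-9]*$", nm),
         two, substr(gsub("[^A-Za-z].*$", "", nm), 1, 1))
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Each `MODEL` record becomes one frame; a file without `MODEL` records is a
#' single-frame trajectory. Atom order must be identical across models.
#' Coordinates are converted from Angstrom to nm. Masses are assigned from
#' the element column when present, otherwise inferred from the atom name.
#'
#' @param path PDB file path.
#' @return A [trajectory()] with frame times `0, 1, 2, ...` (frame units).
#' @export
read_pdb_multimodel <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort(paste0("Empty PDB file: ", path))
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) abort(paste0("No ATOM records in PDB file: ", path))
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0L) {
    groups <- list(which(is_atom))
  } else {
    ends <- c(model_starts[-1] - 1L, length(lines))
    groups <- lapply(seq_along(model_starts), function(i) {
      idx <- model_starts[i]:ends[i]
      idx[is_atom[idx]]
    })
  }
  n_atoms <- length(groups[[1]])
  for (i in seq_along(groups)) {
    if (length(groups[[i]]) != n_atoms) {
      abort(sprintf(
        "Inconsistent atom count in PDB model %d: %d atoms vs %d in model 1.",
        i, length(groups[[i]]), n_atoms))
    }
  }
  first <- lines[groups[[1]]]
  topology <- tibble(
    chain = substr(first, 22, 22),
    resid = as.integer(substr(first, 23, 26)),
    resname = trimws(substr(first, 18, 20)),
    name = trimws(substr(first, 13, 16))
  )
  elem <- trimws(substr(first, 77, 78))
  elem[elem == ""] <- .guess_element(topology$name[elem == ""])
  topology$mass <- .element_mass(elem)
  coords <- array(NA_real_, dim = c(length(groups), n_atoms, 3L))
  for (f in seq_along(groups)) {
    ln <- lines[groups[[f]]]
    coords[f, , 1] <- as.numeric(substr(ln, 31, 38))
    coords[f, , 2] <- as.numeric(substr(ln, 39, 46))
    coords[f, , 3] <- as.numeric(substr(ln, 47, 54))
  }
  if (anyNA(coords)) abort("Malformed coordinate fields in PDB file.")
  trajectory(coords / 10, topology)  # Angstrom -> nm
}

#' Write a trajectory as a multi-model PDB file
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_multimodel <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f) * 10  # nm -> Angstrom
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(top)),
      ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name),
      top$resname, top$chain, top$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], .guess_element(top$name)), con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a plain-text coordinate table plus topology sidecar
#'
#' The coordinate table has one row per frame and `3 * atoms` columns
#' (x1 y1 z1 x2 y2 z2 ...), whitespace- or comma-delimited, in nm. The
#' topology sidecar is a CSV with columns `chain, resid, resname, name, mass`
#' (mass optional if `element` given).
#'
#' @param path Coordinate table path.
#' @param topology_path Topology CSV path.
#' @param times Optional per-frame times (ns).
#' @return A [trajectory()].
#' @export
read_table_traj <- function(path, topology_path, times = NULL) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  if (length(raw) == 0L) abort("Empty coordinate table.")
  split_row <- function(l) as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]])
  rows <- lapply(raw, split_row)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) abort("Ragged coordinate table: unequal row lengths.")
  if (ncols %% 3L != 0L) {
    abort(sprintf("Coordinate column count (%d) is not divisible by 3.", ncols))
  }
  top <- as_tibble(read.csv(topology_path, stringsAsFactors = FALSE))
  if (!"mass" %in% names(top)) {
    if (!"element" %in% names(top)) {
      abort("Topology sidecar needs a `mass` or `element` column.")
    }
    top$mass <- .element_mass(top$element)
  }
  if (!"resname" %in% names(top)) top$resname <- "ALA"
  n_atoms <- ncols %/% 3L
  if (nrow(top) != n_atoms) {
    abort(sprintf("Topology has %d atoms but table implies %d.",
                  nrow(top), n_atoms))
  }
  m <- do.call(rbind, rows)
  coords <- array(NA_real_, dim = c(nrow(m), n_atoms, 3L))
  for (k in 1:3) coords[, , k] <- m[, seq(k, ncols, by = 3L)]
  trajectory(coords, top, times = times)
}

#' Write a trajectory as a coordinate table plus topology sidecar
#' @param traj A [trajectory()].
#' @param path Coordinate table output path.
#' @param topology_path Topology CSV output path.
#' @param digits Significant digits for coordinates (default 17: lossless).
#' @return `path`, invisibly.
#' @export
write_table_traj <- function(traj, path, topology_path, digits = 17L) {
  nf <- n_frames(traj)
  n_atoms <- dim(traj$coords)[2]
  lines <- vapply(seq_len(nf), function(f) {
    xyz <- t(frame_coords(traj, f))  # 3 x atoms, column-major interleave
    paste(format(as.numeric(xyz), digits = digits, trim = TRUE,
                 scientific = TRUE), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  write.csv(traj$topology[, c("chain", "resid", "resname", "name", "mass")],
            topology_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an encoded alignment as FASTA (one record per frame)
#'
#' Header is `frame_<i> t=<time>`; the sequence is the row's letters over
#' fragment positions. [read_sa_fasta()] inverts the operation bit-exactly.
#'
#' @param alignment An [sa_alignment()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_sa_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "sa_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(alignment$letters))) {
    writeLines(sprintf(">frame_%d t=%.6g", f, alignment$times[f]), con)
    writeLines(paste(alignment$letters[f, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read a stacked structural-alphabet alignment from FASTA
#'
#' @param path FASTA path (records = frames, residues = fragment letters).
#' @param fragments Optional fragment map tibble (`column, chain,
#'   first_resid`); defaults to a single chain `"A"` with windows starting at
#'   residue 1, 2, ...
#' @return An [sa_alignment()].
#' @export
read_sa_fasta <- function(path, fragments = NULL) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    seqs <- as.character(ss)
    headers <- names(ss)
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) abort("Not a FASTA file.")
    idx <- cumsum(hdr)
    headers <- sub("^>", "", lines[hdr])
    seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0,
                   character(1), collapse = "")
  }
  if (length(seqs) == 0L) abort("Empty alignment FASTA.")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    abort("Alignment FASTA records have unequal lengths.")
  }
  letters <- do.call(rbind, strsplit(seqs, ""))
  times <- suppressWarnings(
    as.numeric(sub("^.*t=([-0-9.eE+]+).*$", "\\1", headers)))
  if (anyNA(times) || any(diff(times) <= 0)) {
    times <- as.numeric(seq_along(seqs) - 1L)
  }
  if (is.null(fragments)) {
    fragments <- tibble(column = seq_len(ncol(letters)), chain = "A",
                        first_resid = seq_len(ncol(letters)))
  }
  sa_alignment(letters, fragments, times = times, source = path)
}

#' Write a labelled symmetric matrix as CSV
#' @param m Matrix (e.g. a mutual-information matrix's `$values`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
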