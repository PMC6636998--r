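#' Structural alphabet fragment libraries
#'
#' A fragment library is an ordered set of letters, each associated with a
#' prototype geometry of four consecutive Calpha atoms. A chain conformation
#' is coarse-grained by sliding a 4-residue window along the chain and
#' assigning to each position the letter whose prototype superposes onto the
#' observed fragment with minimal Kabsch RMSD.
#'
#' @param letters Character vector of unique single symbols (>= 2).
#' @param prototypes List of 4 x 3 numeric matrices (nm), one per letter.
#' @param name Library label, e.g. `"M32K25-synthetic"`.
#' @return An object of class `fragment_library`.
#' @export
fragment_library <- function(letters, prototypes, name = "custom") {
  letters <- as.character(letters)
  if (length(letters) < 2L) abort("A fragment library needs >= 2 letters.")
  if (anyDuplicated(letters)) abort("Library letters must be unique.")
  if (length(prototypes) != length(letters)) {
    abort("One prototype per letter required.")
  }
  prototypes <- lapply(prototypes, function(p) {
    p <- as.matrix(p)
    if (!all(dim(p) == c(4L, 3L)) || !all(is.finite(p))) {
      abort("Every prototype must be a finite 4 x 3 coordinate matrix.")
    }
    unname(p)
  })
  names(prototypes) <- letters
  structure(
    list(letters = letters, prototypes = prototypes, name = name),
    class = "fragment_library"
  )
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> ", x$name, ": ", length(x$letters),
      " letters (", paste(head(x$letters, 8), collapse = ""),
      if (length(x$letters) > 8) "...", "), 4-Calpha prototypes\n", sep = "")
  invisible(x)
}

#' Read a fragment library from CSV or JSON
#'
#' CSV layout: columns `letter, x1, y1, z1, ..., x4, y4, z4` (nm).
#' JSON layout: object `{name: str, letters: [..], prototypes: [[..12..], ..]}`.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A [fragment_library()].
#' @export
load_library <- function(path) {
  if (!file.exists(path)) abort(paste0("Library file not found: ", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    protos <- lapply(seq_len(nrow(j$prototypes)), function(i) {
      matrix(as.numeric(j$prototypes[i, ]), nrow = 4L, byrow = TRUE)
    })
    return(fragment_library(j$letters, protos,
                            name = j$name %||% "custom"))
  }
  d <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("letter", paste0(rep(c("x", "y", "z"), 4), rep(1:4, each = 3)))
  if (!all(need %in% names(d))) {
    abort("Library CSV must have columns letter, x1,y1,z1, ..., x4,y4,z4.")
  }
  protos <- lapply(seq_len(nrow(d)), function(i) {
    matrix(as.numeric(d[i, need[-1]]), nrow = 4L, byrow = TRUE)
  })
  fragment_library(d$letter, protos,
                   name = attr(d, "name") %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a fragment library to CSV
#' @param library A [fragment_library()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "fragment_library"))
  rows <- lapply(seq_along(library$letters), function(i) {
    p <- library$prototypes[[i]]
    c(list(letter = library$letters[i]),
      as.list(setNames(as.numeric(t(p)),
                       paste0(rep(c("x", "y", "z"), 4), rep(1:4, each = 3)))))
  })
  d <- dplyr::bind_rows(rows)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The bundled default 25-letter fragment library
#'
#' A deterministic synthetic stand-in for the published 25-letter (M32K25)
#' structural alphabet, whose prototype coordinates are defined in prior work
#' and are not redistributed here. The stand-in spans 25 well-separated
#' 4-Calpha geometries with canonical 0.38 nm virtual bond lengths and is
#' adequate for method development and testing; drop in the published
#' coordinates via [load_library()] for production use.
#'
#' @return A [fragment_library()] with 25 letters.
#' @export
default_library <- function() {
  path <- system.file("extdata", "alphabet25_synthetic.csv",
                      package = "allohubr", mustWork = TRUE)
  lib <- load_library(path)
  lib$name <- "M32K25-synthetic"
  lib
}

#' Build a fragment library by k-medoid clustering of observed fragments
#'
#' Clusters supplied 4-Calpha fragments by pairwise minimal Kabsch RMSD
#' (PAM-style build + swap), returning the k medoid geometries as prototypes.
#' Provides a fully self-contained alphabet when no published library is
#' available.
#'
#' @param fragments List of 4 x 3 coordinate matrices (nm).
#' @param k Number of letters.
#' @param letters Optional letter symbols (default `LETTERS`-style sequence).
#' @param max_swaps Maximum swap passes (default 20).
#' @return A [fragment_library()].
#' @export
build_library_from_fragments <- function(fragments, k, letters = NULL,
                                         max_swaps = 20L) {
  n <- length(fragments)
  if (k < 2L || k > n) abort("`k` must be in [2, number of fragments].")
  frc <- lapply(fragments, function(p) sweep(as.matrix(p), 2, colMeans(p)))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- .kabsch_rmsd(frc[[i]], frc[[j]])
    }
  }
  # BUILD: greedy medoid seeding
  med <- integer(0)
  med[1] <- which.min(rowSums(D))
  while (length(med) < k) {
    cur <- apply(D[, med, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(c) {
      if (c %in% med) return(-Inf)
      sum(pmax(cur - D[, c], 0))
    }, numeric(1))
    med <- c(med, which.max(gain))
  }
  cost <- function(m) sum(apply(D[, m, drop = FALSE], 1, min))
  # SWAP
  best <- cost(med)
  for (pass in seq_len(max_swaps)) {
    improved <- FALSE
    for (mi in seq_along(med)) {
      for (c in setdiff(seq_len(n), med)) {
        cand <- med; cand[mi] <- c
        cc <- cost(cand)
        if (cc < best - 1e-12) {
          med <- cand; best <- cc; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  med <- sort(med)
  if (is.null(letters)) letters <- .default_letter_pool(k)
  fragment_library(letters, fragments[med], name = sprintf("kmedoid-%d", k))
}

.default_letter_pool <- function(k) {
  pool <- c(LETTERS, letters)
  if (k > length(pool)) abort("Too many letters requested.")
  pool[seq_len(k)]
}
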