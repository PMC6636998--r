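#' Structural-alphabet encoded alignment
#'
#' The product of encoding a trajectory: a character matrix with one row per
#' frame and one column per fragment position (a 4-residue window; a chain of
#' N residues contributes N - 3 overlapping positions at stride 1), plus a
#' fragment map locating each column in the source topology.
#'
#' @param letters Character matrix `frames x positions`.
#' @param fragments Tibble with columns `column`, `chain`, `first_resid`.
#' @param times Per-frame times (ns).
#' @param library_name Name of the fragment library used.
#' @param source Free-text provenance label.
#' @return An object of class `sa_alignment`.
#' @export
sa_alignment <- function(letters, fragments, times = NULL,
                         library_name = NA_character_, source = NA_character_) {
  letters <- as.matrix(letters)
  fragments <- as_tibble(fragments)
  if (ncol(letters) != nrow(fragments)) {
    abort("One fragment-map row per alignment column required.")
  }
  if (ncol(letters) == 0L || nrow(letters) == 0L) {
    abort("Alignment must have >= 1 frame and >= 1 fragment column.")
  }
  if (is.null(times)) times <- as.numeric(seq_len(nrow(letters)) - 1L)
  structure(
    list(letters = unname(letters), fragments = fragments,
         times = as.numeric(times), library_name = library_name,
         source = source),
    class = "sa_alignment"
  )
}

#' @export
print.sa_alignment <- function(x, ...) {
  cat(sprintf(
    "<sa_alignment> %d frames x %d fragment positions (%d chain(s), library %s)\n",
    nrow(x$letters), ncol(x$letters), length(unique(x$fragments$chain)),
    x$library_name))
  invisible(x)
}

#' @export
dim.sa_alignment <- function(x) dim(x$letters)

#' @export
as_tibble.sa_alignment <- function(x, ...) {
  tibble(
    frame = rep(seq_len(nrow(x$letters)), times = ncol(x$letters)),
    column = rep(x$fragments$column, each = nrow(x$letters)),
    chain = rep(x$fragments$chain, each = nrow(x$letters)),
    first_resid = rep(x$fragments$first_resid, each = nrow(x$letters)),
    letter = as.vector(x$letters)
  )
}

#' Encode one chain conformation as a string of fragment letters
#'
#' Slides a 4-residue window along the chain (stride 1) and assigns each
#' window the library letter whose prototype superposes with minimal Kabsch
#' RMSD. Ties are broken towards the lower library index, so encoding is
#' deterministic; encoding a prototype's own geometry returns its letter.
#'
#' @param coords Numeric N x 3 matrix of Calpha coordinates for one frame
#'   (nm), N >= 4, residues in chain order.
#' @param library A [fragment_library()].
#' @return Character vector of length N - 3 (one letter per window).
#' @export
encode_chain <- function(coords, library) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4L) abort("Chain must have >= 4 residues to encode.")
  if (!all(is.finite(coords))) {
    bad <- which(!is.finite(rowSums(coords)))[1]
    abort(sprintf("Non-finite coordinates at residue position %d.", bad))
  }
  cache <- .proto_cache(library)
  out <- character(n - 3L)
  for (i in seq_len(n - 3L)) {
    w <- coords[i:(i + 3L), , drop = FALSE]
    w <- sweep(w, 2, colMeans(w))
    r <- .rmsd_to_protos(w, cache)
    out[i] <- library$letters[which.min(r)]  # which.min: lowest index on ties
  }
  out
}

## Precomputed centred prototype block for the vectorised assignment.
.proto_cache <- function(library) {
  protos <- lapply(library$prototypes, function(p) sweep(p, 2, colMeans(p)))
  list(Qcat = do.call(cbind, protos),                    # 4 x 3K
       q2 = vapply(protos, function(p) sum(p^2), numeric(1)),
       K = length(protos))
}

## RMSD of one centred 4x3 window against all K prototypes at once.
## Uses max_R tr(R H) = s1 + s2 + sign(det H) s3 with the singular values
## obtained from the closed-form (trigonometric) eigenvalues of H^T H,
## avoiding K LAPACK calls per window. Agrees with the SVD route to
## round-off (property-tested against kabsch_superpose()).
.rmsd_to_protos <- function(w, cache) {
  K <- cache$K
  H <- crossprod(w, cache$Qcat)        # 3 x 3K; columns a_k, b_k, c_k
  a <- H[, seq(1L, 3L * K, 3L), drop = FALSE]
  b <- H[, seq(2L, 3L * K, 3L), drop = FALSE]
  c_ <- H[, seq(3L, 3L * K, 3L), drop = FALSE]
  B11 <- colSums(a * a); B22 <- colSums(b * b); B33 <- colSums(c_ * c_)
  B12 <- colSums(a * b); B13 <- colSums(a * c_); B23 <- colSums(b * c_)
  detH <- a[1, ] * (b[2, ] * c_[3, ] - b[3, ] * c_[2, ]) -
          a[2, ] * (b[1, ] * c_[3, ] - b[3, ] * c_[1, ]) +
          a[3, ] * (b[1, ] * c_[2, ] - b[2, ] * c_[1, ])
  q <- (B11 + B22 + B33) / 3
  p2 <- (B11 - q)^2 + (B22 - q)^2 + (B33 - q)^2 +
    2 * (B12^2 + B13^2 + B23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  # det(B - qI)
  d11 <- B11 - q; d22 <- B22 - q; d33 <- B33 - q
  detBq <- d11 * (d22 * d33 - B23^2) - B12 * (B12 * d33 - B23 * B13) +
    B13 * (B12 * B23 - d22 * B13)
  r <- ifelse(p > 0, detBq / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- pmax(3 * q - l1 - l3, 0)
  s <- sqrt(pmax(l1, 0)) + sqrt(l2) + sign(detH) * sqrt(pmax(l3, 0))
  sqrt(pmax(sum(w^2) + cache$q2 - 2 * s, 0) / 4)
}

#' Encode a whole trajectory into a stacked structural-alphabet alignment
#'
#' Every frame of every encodable chain is coarse-grained with
#' [encode_chain()]; per-chain encodings are concatenated column-wise so each
#' row is the letter string of one frame. The fragment map records, for every
#' column, the chain and the first residue of the 4-residue window, so
#' per-chain sub-alignments remain recoverable.
#'
#' @param traj A [trajectory()].
#' @param library A [fragment_library()] (default [default_library()]).
#' @param chains Optional chain ids to encode (default: all encodable).
#' @return An [sa_alignment()].
#' @export
encode_trajectory <- function(traj, library = default_library(),
                              chains = NULL) {
  sel <- select_calpha(traj)
  if (!is.null(chains)) {
    sel <- sel[sel$chain %in% chains, ]
    if (nrow(sel) == 0L) abort("None of the requested chains are encodable.")
  }
  nf <- n_frames(traj)
  frag_map <- purrr::pmap_dfr(sel, function(chain, n_res, atom_idx, resid) {
    tibble(chain = chain, first_resid = resid[seq_len(n_res - 3L)])
  })
  frag_map$column <- seq_len(nrow(frag_map))
  frag_map <- frag_map[, c("column", "chain", "first_resid")]
  letters <- matrix(NA_character_, nrow = nf, ncol = nrow(frag_map))
  for (f in seq_len(nf)) {
    fc <- frame_coords(traj, f)
    row <- unlist(lapply(seq_len(nrow(sel)), function(ci) {
      tryCatch(
        encode_chain(fc[sel$atom_idx[[ci]], , drop = FALSE], library),
        error = function(e) {
          abort(sprintf("Encoding failed in frame %d, chain %s: %s",
                        f, sel$chain[ci], conditionMessage(e)))
        })
    }))
    letters[f, ] <- row
  }
  sa_alignment(letters, frag_map, times = traj$times,
               library_name = library$name)
}

#' Extract the columns of one chain from a stacked alignment
#' @param alignment An [sa_alignment()].
#' @param chain Chain id.
#' @return An [sa_alignment()] restricted to that chain's columns.
#' @export
chain_alignment <- function(alignment, chain) {
  keep <- alignment$fragments$chain == chain
  if (!any(keep)) abort(paste0("Unknown chain: ", chain))
  sa_alignment(alignment$letters[, keep, drop = FALSE],
               alignment$fragments[keep, ],
               times = alignment$times,
               library_name = alignment$library_name,
               source = alignment$source)
}
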