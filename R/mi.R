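#' Finite-size-corrected normalised mutual information of two letter columns
#'
#' For two columns \eqn{C_i, C_j} of a structural-alphabet alignment with
#' joint frequencies \eqn{p(c_i, c_j)}, the plug-in mutual information is
#' \deqn{I = \sum p(c_i,c_j) \ln[p(c_i,c_j) / (p(c_i) p(c_j))]}
#' and the joint entropy \eqn{H = -\sum p(c_i,c_j) \ln p(c_i,c_j)} (natural
#' logarithms; zero-probability cells contribute 0). The finite-sample bias
#' of the plug-in estimator is corrected with
#' \deqn{\epsilon = (B_{ij} - B_i - B_j + 1) / (2N)}
#' where \eqn{B_{ij}, B_i, B_j} count joint and marginal states of non-zero
#' probability and \eqn{N} is the sample size. The normalised value is
#' \eqn{nMI = (I - \epsilon)/H}, clamped to \eqn{[0, 1]} (the correction can
#' push the raw ratio outside the unit interval); if both columns are
#' constant (\eqn{H = 0}), nMI is 0 by convention.
#'
#' @param ci,cj Equal-length character (or factor) vectors, length >= 2.
#' @return A one-row tibble with columns `I`, `H`, `eps`, `nmi_raw`, `nmi`,
#'   `N`, `Bij`, `Bi`, `Bj` (information quantities in nats).
#' @examples
#' x <- rep(c("A", "B"), 100)
#' column_mi(x, x)   # identical two-state columns: nMI clamps to 1
#' @export
column_mi <- function(ci, cj) {
  ci <- as.character(ci); cj <- as.character(cj)
  if (length(ci) != length(cj)) abort("`ci` and `cj` must have equal length.")
  n <- length(ci)
  if (n < 2L) abort("Need N >= 2 observations.")
  tab <- table(ci, cj)
  pj <- tab / n
  pi_ <- rowSums(pj); pj_ <- colSums(pj)
  nz <- pj > 0
  outer_p <- outer(pi_, pj_)
  I <- sum(pj[nz] * log(pj[nz] / outer_p[nz]))
  H <- -sum(pj[nz] * log(pj[nz]))
  Bij <- sum(nz); Bi <- sum(pi_ > 0); Bj <- sum(pj_ > 0)
  eps <- (Bij - Bi - Bj + 1) / (2 * n)
  nmi_raw <- if (H > 0) (I - eps) / H else 0
  tibble(I = I, H = H, eps = eps, nmi_raw = nmi_raw,
         nmi = min(max(nmi_raw, 0), 1),
         N = n, Bij = Bij, Bi = Bi, Bj = Bj)
}

#' Mutual-information matrix container
#'
#' Symmetric fragment-pair matrix of normalised mutual information with
#' provenance (state, replica, block, chain, frame range) and an optional
#' mask of sequence-overlapping fragment pairs.
#'
#' @param values Symmetric numeric matrix, entries in `[0, 1]`, zero diagonal.
#' @param fragments Fragment map tibble (`column, chain, first_resid`) for
#'   the rows/columns.
#' @param provenance Named list (free-form: `state`, `replica`, `block`,
#'   `chain`, `frames`).
#' @param mask Logical matrix, `TRUE` where a pair is masked (excluded from
#'   analysis); defaults to diagonal-only.
#' @return An object of class `mi_matrix`.
#' @export
mi_matrix <- function(values, fragments, provenance = list(), mask = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("MI matrix must be square.")
  if (max(abs(values - t(values))) > 1e-10) abort("MI matrix must be symmetric.")
  fragments <- as_tibble(fragments)
  if (nrow(fragments) != nrow(values)) {
    abort("Fragment map must match matrix dimension.")
  }
  if (is.null(mask)) mask <- diag(nrow(values)) == 1
  diag(values) <- 0
  labs <- paste0(fragments$chain, fragments$first_resid)
  dimnames(values) <- list(labs, labs)
  structure(list(values = values, fragments = fragments,
                 provenance = provenance, mask = mask),
            class = "mi_matrix")
}

#' @export
print.mi_matrix <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("<mi_matrix> %d x %d fragments%s; mean off-diag nMI %.4f\n",
              nrow(x$values), ncol(x$values),
              if (length(pv)) paste0(" [",
                paste(names(pv), unlist(lapply(pv, function(v)
                  paste(format(v), collapse = ":"))), sep = "=",
                  collapse = ", "), "]") else "",
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' @export
as_tibble.mi_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(
    i = ut[, 1], j = ut[, 2],
    frag_i = rownames(x$values)[ut[, 1]],
    frag_j = colnames(x$values)[ut[, 2]],
    nmi = x$values[ut],
    masked = x$mask[ut]
  )
}

#' All-pairs nMI matrix for one chain over a frame range
#'
#' Computes [column_mi()] for every pair of fragment columns of the given
#' chain, restricted to a frame range (a trajectory block). Pairs of
#' sequence-overlapping fragments (window starts closer than 4 residues, so
#' the windows share residues and are trivially correlated) are masked and
#' set to 0 by default.
#'
#' @param alignment An [sa_alignment()].
#' @param frames Integer vector of frame indices (default: all frames).
#' @param chain Chain id (default: the only chain; required if several).
#' @param mask_overlap Mask pairs with `|first_resid_i - first_resid_j| <= 3`
#'   on the same chain (default `TRUE`).
#' @param provenance Named list merged into the result's provenance.
#' @return An [mi_matrix()].
#' @export
block_mi_matrix <- function(alignment, frames = NULL, chain = NULL,
                            mask_overlap = TRUE, provenance = list()) {
  stopifnot(inherits(alignment, "sa_alignment"))
  if (is.null(chain)) {
    ch <- unique(alignment$fragments$chain)
    if (length(ch) > 1L) abort("Several chains present; specify `chain`.")
    chain <- ch
  }
  sub <- chain_alignment(alignment, chain)
  if (is.null(frames)) frames <- seq_len(nrow(sub$letters))
  if (length(frames) == 0L || any(frames < 1L) ||
      any(frames > nrow(sub$letters))) {
    abort("Empty or out-of-range frame selection.")
  }
  L <- sub$letters[frames, , drop = FALSE]
  p <- ncol(L)
  vals <- matrix(0, p, p)
  mask <- matrix(FALSE, p, p)
  fr <- sub$fragments$first_resid
  for (i in seq_len(p)) {
    mask[i, i] <- TRUE
    if (i == p) next
    for (j in (i + 1L):p) {
      if (mask_overlap && abs(fr[i] - fr[j]) <= 3L) {
        mask[i, j] <- mask[j, i] <- TRUE
        next
      }
      vals[i, j] <- vals[j, i] <- column_mi(L[, i], L[, j])$nmi
    }
  }
  mi_matrix(vals, sub$fragments,
            provenance = c(list(chain = chain, frames = range(frames)),
                           provenance),
            mask = mask)
}

#' Per-fragment positional entropy of an encoded alignment
#'
#' Shannon entropy (nats) of the letter frequencies of each fragment column
#' over the selected frames. High positional entropy marks conformationally
#' flexible backbone segments; across fragments it correlates with total
#' coupling strength.
#'
#' @param alignment An [sa_alignment()].
#' @param frames Frame selection (default all).
#' @return Tibble with columns `column`, `chain`, `first_resid`, `entropy`.
#' @export
positional_entropy <- function(alignment, frames = NULL) {
  stopifnot(inherits(alignment, "sa_alignment"))
  if (is.null(frames)) frames <- seq_len(nrow(alignment$letters))
  if (length(frames) == 0L) abort("Empty frame selection.")
  L <- alignment$letters[frames, , drop = FALSE]
  ent <- apply(L, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log(p))
  })
  dplyr::mutate(alignment$fragments, entropy = as.numeric(ent))
}

#' Total coupling strength of fragments in an nMI matrix
#'
#' Sums a fragment's nMI over all unmasked partners (its network degree
#' strength). With `fragment = NULL`, returns the whole profile.
#'
#' @param mi An [mi_matrix()] (or an `ensemble_network`).
#' @param fragment Optional column index or fragment label.
#' @return Single numeric if `fragment` given, else a tibble
#'   (`column, chain, first_resid, total_nmi`).
#' @export
fragment_total_mi <- function(mi, fragment = NULL) {
  if (inherits(mi, "ensemble_network")) {
    mi <- mi_matrix(mi$matrix, mi$fragments, mask = mi$mask)
  }
  stopifnot(inherits(mi, "mi_matrix"))
  v <- mi$values
  v[mi$mask] <- 0
  totals <- rowSums(v)
  if (is.null(fragment)) {
    return(dplyr::mutate(mi$fragments, total_nmi = as.numeric(totals)))
  }
  if (is.character(fragment)) {
    idx <- match(fragment, rownames(mi$values))
  } else {
    idx <- as.integer(fragment)
    if (idx < 1L || idx > nrow(v)) idx <- NA_integer_
  }
  if (is.na(idx)) abort(paste0("Unknown fragment: ", fragment))
  as.numeric(totals[idx])
}
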