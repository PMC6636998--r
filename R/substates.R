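#' Split frames into contiguous, length-balanced trajectory blocks
#'
#' Divides the frame range into `n_blocks` contiguous, non-overlapping
#' blocks; when the frame count is not divisible, the remainder `r` is
#' distributed one extra frame to each of the first `r` blocks. Block-wise
#' coupling matrices are the raw material of substate detection (the
#' reference analysis used 20 blocks of 20 ns over each 400 ns trajectory).
#'
#' @param x An [sa_alignment()], [trajectory()], or integer frame count.
#' @param n_blocks Number of blocks (1 <= n_blocks <= frames).
#' @return Tibble with columns `block`, `start`, `end`, `n`.
#' @export
split_blocks <- function(x, n_blocks) {
  nf <- if (inherits(x, "sa_alignment")) nrow(x$letters)
        else if (inherits(x, "Trajectory")) n_frames(x)
        else as.integer(x)
  n_blocks <- as.integer(n_blocks)
  if (is.na(nf) || nf < 1L) abort("Invalid frame count.")
  if (n_blocks < 1L || n_blocks > nf) {
    abort(sprintf("`n_blocks` must be in [1, %d].", nf))
  }
  base <- nf %/% n_blocks
  r <- nf %% n_blocks
  sizes <- rep(base, n_blocks) + c(rep(1L, r), rep(0L, n_blocks - r))
  end <- cumsum(sizes)
  tibble(block = seq_len(n_blocks), start = end - sizes + 1L, end = end,
         n = sizes)
}

#' Covariance matrix overlap of two symmetric matrices
#'
#' Spectral similarity used both to delimit conformational substates in time
#' and as the distance (1 - omega) for clustering substate matrices. With
#' eigendecompositions \eqn{A = \sum \lambda_i^A v_i^A v_i^{A\top}} (negative
#' eigenvalues clipped to 0 — coupling matrices are symmetric but not
#' guaranteed PSD; the clipped magnitude is recorded and warned about above
#' 1% of the trace),
#' \deqn{d(A,B) = \sqrt{tr A + tr B - 2\, tr(A^{1/2} B^{1/2})}, \quad
#'       tr(A^{1/2}B^{1/2}) = \sum_{ij} \sqrt{\lambda_i^A \lambda_j^B}
#'       (v_i^A \cdot v_j^B)^2}
#' \deqn{\Omega_{A;B} = 1 - d(A,B) / \sqrt{tr A + tr B}}
#' Omega is 1 for identical matrices, 0 for orthogonal ones, and is clamped
#' to `[0, 1]` against round-off. Two all-zero matrices are defined as
#' identical (omega = 1).
#'
#' @param A,B [mi_matrix()] objects or plain symmetric matrices of equal
#'   dimension.
#' @param warn Warn when the clipped magnitude exceeds 1% of the retained
#'   trace (default `TRUE`). Batch callers working on hollow
#'   (zero-diagonal) coupling matrices, which are indefinite by
#'   construction, disable the warning; the magnitude is still returned.
#' @return List with `omega`, `d`, `eigvals_a`, `eigvals_b`,
#'   `psd_adjustment` (summed magnitude of clipped negative eigenvalues).
#' @export
covariance_overlap <- function(A, B, warn = TRUE) {
  A <- if (inherits(A, "mi_matrix")) A$values else as.matrix(A)
  B <- if (inherits(B, "mi_matrix")) B$values else as.matrix(B)
  if (!all(dim(A) == dim(B))) abort("Matrices must have equal dimensions.")
  if (max(abs(A - t(A))) > 1e-8 || max(abs(B - t(B))) > 1e-8) {
    abort("Matrices must be symmetric.")
  }
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  eb <- eigen((B + t(B)) / 2, symmetric = TRUE)
  clipped <- sum(abs(pmin(ea$values, 0))) + sum(abs(pmin(eb$values, 0)))
  la <- pmax(ea$values, 0); lb <- pmax(eb$values, 0)
  tra <- sum(la); trb <- sum(lb)
  if (warn && clipped > 0.01 * max(tra + trb, .Machine$double.eps)) {
    warn(sprintf(
      "Negative eigenvalues clipped (summed magnitude %.3g, >1%% of trace).",
      clipped))
  }
  if (tra + trb < 1e-300) {
    return(list(omega = 1, d = 0, eigvals_a = la, eigvals_b = lb,
                psd_adjustment = clipped))
  }
  # tr(A^{1/2} B^{1/2}) via the eigenvector cross-products
  Vt <- crossprod(ea$vectors, eb$vectors)   # (v_i^A . v_j^B)
  cross <- sum(outer(sqrt(la), sqrt(lb)) * Vt^2)
  d2 <- max(tra + trb - 2 * cross, 0)
  d <- sqrt(d2)
  omega <- min(max(1 - d / sqrt(tra + trb), 0), 1)
  if (d2 < 1e-24) omega <- 1
  list(omega = omega, d = d, eigvals_a = la, eigvals_b = lb,
       psd_adjustment = clipped)
}

#' Segment time-ordered block matrices into conformational substates
#'
#' Greedy left-to-right run building: block `t + 1` joins the current run iff
#' the covariance overlap between the run's representative (running mean
#' matrix) and block `t + 1` is at least `omega_threshold`; otherwise a new
#' run starts. Runs shorter than `min_run` are then merged into the
#' neighbouring run with the higher overlap. Each resulting substate carries
#' the mean matrix of its member blocks and an occupancy probability
#' (member blocks / total blocks).
#'
#' @param blocks List of [mi_matrix()] (or plain symmetric matrices) in time
#'   order.
#' @param omega_threshold Overlap threshold in (0, 1] (default 0.85; the
#'   level of "high similarity" is necessarily a tuning parameter).
#' @param min_run Minimum blocks per substate (default 2).
#' @return An object of class `substate_set`: tibble `$substates` with
#'   columns `substate`, `blocks` (list), `n_blocks`, `probability`,
#'   `representative` (list of matrices), plus parameters and provenance.
#' @export
segment_substates <- function(blocks, omega_threshold = 0.85, min_run = 2L) {
  if (length(blocks) == 0L) abort("Need >= 1 block matrix.")
  if (omega_threshold <= 0 || omega_threshold > 1) {
    abort("`omega_threshold` must be in (0, 1].")
  }
  fragments <- if (inherits(blocks[[1]], "mi_matrix")) blocks[[1]]$fragments
  mats <- lapply(blocks, function(b)
    if (inherits(b, "mi_matrix")) b$values else as.matrix(b))
  nb <- length(mats)
  runs <- list(1L)
  rep_mat <- mats[[1]]
  for (t in seq_len(nb - 1L)) {
    om <- covariance_overlap(rep_mat, mats[[t + 1L]], warn = FALSE)$omega
    k <- length(runs)
    if (om >= omega_threshold) {
      runs[[k]] <- c(runs[[k]], t + 1L)
      rep_mat <- Reduce(`+`, mats[runs[[k]]]) / length(runs[[k]])
    } else {
      runs[[k + 1L]] <- t + 1L
      rep_mat <- mats[[t + 1L]]
    }
  }
  # merge short runs into the neighbour with higher overlap to the run mean
  run_mean <- function(r) Reduce(`+`, mats[r]) / length(r)
  repeat {
    lens <- lengths(runs)
    if (length(runs) <= 1L || all(lens >= min_run)) break
    s <- which.min(ifelse(lens < min_run, lens, Inf))
    m <- run_mean(runs[[s]])
    om_prev <- if (s > 1L) covariance_overlap(m, run_mean(runs[[s - 1L]]), warn = FALSE)$omega else -Inf
    om_next <- if (s < length(runs)) covariance_overlap(m, run_mean(runs[[s + 1L]]), warn = FALSE)$omega else -Inf
    tgt <- if (om_prev >= om_next) s - 1L else s + 1L
    runs[[min(s, tgt)]] <- sort(c(runs[[s]], runs[[tgt]]))
    runs[[max(s, tgt)]] <- NULL
  }
  st <- tibble(
    substate = seq_along(runs),
    blocks = runs,
    n_blocks = lengths(runs),
    probability = lengths(runs) / nb,
    representative = lapply(runs, run_mean)
  )
  structure(list(substates = st, n_blocks = nb,
                 omega_threshold = omega_threshold, min_run = min_run,
                 fragments = fragments),
            class = "substate_set")
}

#' @export
print.substate_set <- function(x, ...) {
  cat(sprintf(
    "<substate_set> %d substate(s) over %d blocks (omega >= %.2f, min_run %d)\n",
    nrow(x$substates), x$n_blocks, x$omega_threshold, x$min_run))
  print(dplyr::select(x$substates, "substate", "n_blocks", "probability"))
  invisible(x)
}

#' @export
tidy.substate_set <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$substates, "substate", "n_blocks", "probability"),
    first_block = vapply(x$substates$blocks, min, integer(1)),
    last_block = vapply(x$substates$blocks, max, integer(1))
  )
}

#' @export
glance.substate_set <- function(x, ...) {
  tibble(n_substates = nrow(x$substates), n_blocks = x$n_blocks,
         omega_threshold = x$omega_threshold, min_run = x$min_run,
         max_probability = max(x$substates$probability))
}

#' Complete-linkage clustering of substate matrices
#'
#' Compares coupling matrices pooled across replicas/states with the
#' covariance overlap as similarity (distance `1 - omega`) and agglomerates
#' with complete linkage. Matrices from the same liganded state are expected
#' to co-cluster.
#'
#' @param matrices List of [mi_matrix()] / matrices (equal dimension), >= 2.
#' @param labels Optional labels (e.g. `"apo_r1_s2"`); default `m1, m2, ...`
#' @param cut_h Flat-cluster cut height on `1 - omega` (default `NULL`: no
#'   flat labels).
#' @param k Alternative: number of flat clusters.
#' @return List with `hclust` (a [stats::hclust] tree), `dist` (the
#'   `1 - omega` distance matrix), `clusters` (named integer vector or
#'   `NULL`), `order` (heatmap leaf order).
#' @export
cluster_substates <- function(matrices, labels = NULL, cut_h = NULL, k = NULL) {
  n <- length(matrices)
  if (n < 2L) abort("Need >= 2 matrices to cluster.")
  if (is.null(labels)) labels <- paste0("m", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- 1 - covariance_overlap(matrices[[i]],
                                                   matrices[[j]],
                                                   warn = FALSE)$omega
    }
  }
  hc <- hclust(stats::as.dist(D), method = "complete")
  clusters <- if (!is.null(k)) cutree(hc, k = k)
              else if (!is.null(cut_h)) cutree(hc, h = cut_h)
  list(hclust = hc, dist = D, clusters = clusters, order = hc$order)
}
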