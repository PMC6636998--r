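#' Mass-weighted positional covariance of a trajectory
#'
#' Computes \eqn{\sigma_{ij} = \langle (x_i - \langle x_i\rangle)
#' (x_j - \langle x_j\rangle) \rangle} over frames for the 3n Cartesian
#' coordinates of the selected atoms, mass-weighted as
#' \eqn{\sqrt{m_i m_j}\,\sigma_{ij}} (so the matrix is
#' \eqn{M^{1/2} \sigma M^{1/2}} in kg m^2). By default every frame is first
#' least-squares superposed onto the mean structure (iterated Kabsch fit) to
#' remove rigid-body translation/rotation, which would otherwise dominate
#' the apparent configurational fluctuations.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param selection `"calpha"` (default), `"all"`, or an integer atom index
#'   vector.
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @param max_iter Superposition iterations (default 5).
#' @return Symmetric 3n x 3n matrix (kg m^2) with attributes `atoms`
#'   (indices used), `superposed`, `n_frames`.
#' @export
mass_weighted_covariance <- function(traj, selection = "calpha",
                                     superpose = TRUE, max_iter = 5L) {
  stopifnot(inherits(traj, "Trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) abort("Need >= 2 frames for a covariance estimate.")
  atoms <- if (is.numeric(selection)) {
    as.integer(selection)
  } else if (identical(selection, "all")) {
    seq_len(dim(traj$coords)[2])
  } else if (identical(selection, "calpha")) {
    which(traj$topology$name == "CA")
  } else {
    abort("`selection` must be 'calpha', 'all', or atom indices.")
  }
  if (!length(atoms)) abort("Empty atom selection.")
  n <- length(atoms)
  # frames x (3n) coordinate matrix in metres
  X <- matrix(NA_real_, nf, 3L * n)
  for (f in seq_len(nf)) {
    X[f, ] <- as.numeric(t(frame_coords(traj, f)[atoms, , drop = FALSE]))
  }
  X <- X * 1e-9  # nm -> m
  if (superpose && n >= 3L) {
    ref <- matrix(colMeans(X), ncol = 3L, byrow = TRUE)
    for (it in seq_len(max_iter)) {
      for (f in seq_len(nf)) {
        P <- matrix(X[f, ], ncol = 3L, byrow = TRUE)
        fit <- kabsch_superpose(P, ref)
        Pc <- sweep(P, 2, colMeans(P))
        X[f, ] <- as.numeric(t(sweep(Pc %*% t(fit$rotation), 2,
                                     colMeans(ref), `+`)))
      }
      new_ref <- matrix(colMeans(X), ncol = 3L, byrow = TRUE)
      if (max(abs(new_ref - ref)) < 1e-15) break
      ref <- new_ref
    }
  }
  Xc <- sweep(X, 2, colMeans(X))
  sigma <- crossprod(Xc) / nf
  m <- rep(traj$topology$mass[atoms], each = 3L) * .const$amu  # kg
  w <- sqrt(m)
  mw <- sigma * tcrossprod(w)
  mw <- (mw + t(mw)) / 2
  structure(mw, atoms = atoms, superposed = superpose, n_frames = nf)
}

#' Schlitter upper bound on configurational entropy
#'
#' Evaluates the Schlitter formula
#' \deqn{S' = \frac{k_B}{2} \ln \det\left(1 +
#'   \frac{k_B T e^2}{\hbar^2} M^{1/2} \sigma M^{1/2}\right)}
#' via the eigenvalues of the mass-weighted covariance matrix (negative
#' eigenvalues, numerical artefacts of finite sampling, are clipped to 0 and
#' recorded). `S'` is an upper bound to the true configurational entropy; a
#' rigid trajectory (zero covariance) gives exactly 0, and each independent
#' harmonic mode contributes additively.
#'
#' @param covariance Mass-weighted covariance matrix (kg m^2), e.g. from
#'   [mass_weighted_covariance()].
#' @param temperature Temperature in K (default 300).
#' @return An object of class `entropy_result`: list with `S` (J K^-1
#'   mol^-1), `S_molecule` (J K^-1 per molecule), `S_kB` (in units of k_B),
#'   `temperature`, `n_modes`, `clipped` (summed magnitude of clipped
#'   negative eigenvalues), `eigenvalues`.
#' @export
schlitter_entropy <- function(covariance, temperature = 300) {
  if (temperature <= 0) abort("Temperature must be > 0 K.")
  covariance <- as.matrix(covariance)
  if (max(abs(covariance - t(covariance))) >
      1e-8 * max(abs(covariance), 1e-300)) {
    abort("Covariance matrix must be symmetric.")
  }
  ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  clipped <- sum(abs(pmin(ev, 0)))
  lam <- pmax(ev, 0)
  alpha <- .const$kB * temperature * exp(1)^2 / .const$hbar^2
  s_molecule <- (.const$kB / 2) * sum(log1p(alpha * lam))
  structure(
    list(S = s_molecule * .const$NA_, S_molecule = s_molecule,
         S_kB = s_molecule / .const$kB, temperature = temperature,
         n_modes = length(lam), clipped = clipped, eigenvalues = lam),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "<entropy_result> S' = %.4g J K^-1 mol^-1 (%.4g kB/molecule) at %g K over %d modes\n",
    x$S, x$S_kB, x$temperature, x$n_modes))
  invisible(x)
}

#' @export
glance.entropy_result <- function(x, ...) {
  tibble(S = x$S, S_kB = x$S_kB, temperature = x$temperature,
         n_modes = x$n_modes, clipped = x$clipped)
}

#' One-call Schlitter entropy of a trajectory
#' @inheritParams mass_weighted_covariance
#' @inheritParams schlitter_entropy
#' @return An `entropy_result` (see [schlitter_entropy()]).
#' @export
trajectory_entropy <- function(traj, selection = "calpha",
                               temperature = 300, superpose = TRUE) {
  schlitter_entropy(
    mass_weighted_covariance(traj, selection, superpose = superpose),
    temperature = temperature)
}
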