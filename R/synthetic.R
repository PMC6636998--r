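## Synthetic ground-truth generator.
##
## Emulates the statistical structure the pipeline assumes: each chain is a
## sequence of non-overlapping 4-residue fragment slots that interconvert
## between discrete conformers; selected slot pairs switch in a correlated
## way (shared-flip model), and the coupling pattern may change between
## temporal regimes. All draws are governed by a mandatory seed.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic fragment-conformer world
#'
#' @param n_fragments Planted fragment slots per chain (each slot is a
#'   non-overlapping 4-residue segment, so a chain has `4 * n_fragments`
#'   residues).
#' @param chains Number of chains (protomers); couplings replicate per chain
#'   with independent draws.
#' @param frames Number of frames.
#' @param n_conformers Discrete conformers per slot (default 2).
#' @param couplings Tibble with columns `i`, `j` (slot indices) and `rho`
#'   in `[0, 1]`: with probability `rho` slot `j` copies slot `i`'s state,
#'   otherwise it is independent, so a coupled pair shares its state with
#'   probability `(1 + rho) / 2` in the binary case.
#' @param regimes Optional list of `list(frames = c(first, last),
#'   couplings = <tibble>)` overriding `couplings` over frame windows; the
#'   windows must partition `1:frames`.
#' @param noise Gaussian coordinate noise sd (nm) for geometric emission
#'   (default 0).
#' @param seed Mandatory RNG seed.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_fragments = 10L, chains = 1L, frames = 400L,
                     n_conformers = 2L, couplings = NULL, regimes = NULL,
                     noise = 0, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    abort("`seed` is mandatory for a sim_spec.")
  }
  if (is.null(couplings)) {
    couplings <- tibble(i = integer(), j = integer(), rho = numeric())
  }
  couplings <- as_tibble(couplings)
  check_coup <- function(cp) {
    if (nrow(cp) == 0L) return(invisible())
    if (any(cp$rho < 0 | cp$rho > 1)) abort("Coupling rho must be in [0, 1].")
    if (any(cp$i < 1L | cp$i > n_fragments | cp$j < 1L | cp$j > n_fragments))
      abort("Coupling slot indices out of range.")
    if (any(cp$i == cp$j)) abort("Self-couplings are not allowed.")
  }
  check_coup(couplings)
  if (!is.null(regimes)) {
    covered <- integer(0)
    for (rg in regimes) {
      if (!is.list(rg) || is.null(rg$frames) || length(rg$frames) != 2L) {
        abort("Each regime needs `frames = c(first, last)`.")
      }
      check_coup(as_tibble(rg$couplings))
      covered <- c(covered, rg$frames[1]:rg$frames[2])
    }
    if (!identical(sort(covered), seq_len(frames))) {
      abort("Regime windows must partition 1:frames without overlap.")
    }
  }
  if (n_conformers < 2L) abort("Need >= 2 conformers per slot.")
  structure(
    list(n_fragments = as.integer(n_fragments), chains = as.integer(chains),
         frames = as.integer(frames), n_conformers = as.integer(n_conformers),
         couplings = couplings, regimes = regimes, noise = noise,
         seed = as.integer(seed)),
    class = "sim_spec"
  )
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> %d chain(s) x %d slots x %d frames, %d conformers, %d coupling(s), %d regime(s), noise %g nm, seed %d\n",
    x$chains, x$n_fragments, x$frames, x$n_conformers, nrow(x$couplings),
    length(x$regimes) %||% 1L, x$noise, x$seed))
  invisible(x)
}

## frame -> active coupling table
.regime_of_frame <- function(spec) {
  if (is.null(spec$regimes)) {
    return(list(id = rep(1L, spec$frames), couplings = list(spec$couplings)))
  }
  id <- integer(spec$frames)
  cps <- vector("list", length(spec$regimes))
  for (r in seq_along(spec$regimes)) {
    rg <- spec$regimes[[r]]
    id[rg$frames[1]:rg$frames[2]] <- r
    cps[[r]] <- as_tibble(rg$couplings)
  }
  list(id = id, couplings = cps)
}

## latent conformer states: frames x (chains * n_fragments) integer matrix
.draw_states <- function(spec) {
  reg <- .regime_of_frame(spec)
  K <- spec$n_conformers
  S <- matrix(NA_integer_, spec$frames, spec$chains * spec$n_fragments)
  for (f in seq_len(spec$frames)) {
    cp <- reg$couplings[[reg$id[f]]]
    for (ch in seq_len(spec$chains)) {
      st <- sample.int(K, spec$n_fragments, replace = TRUE)
      if (nrow(cp)) {
        for (r in seq_len(nrow(cp))) {
          if (stats::runif(1) < cp$rho[r]) st[cp$j[r]] <- st[cp$i[r]]
        }
      }
      S[f, (ch - 1L) * spec$n_fragments + seq_len(spec$n_fragments)] <- st
    }
  }
  attr(S, "regime_id") <- reg$id
  S
}

#' Simulate a pre-encoded alignment with planted couplings
#'
#' Emits one alignment column per fragment slot (no geometry involved):
#' conformer `k` of every slot maps to library letter `k`. Returns the
#' alignment together with the complete ground truth, so coupling-recovery
#' and regime-recovery tests need no external data.
#'
#' @param spec A [sim_spec()].
#' @param letters_pool Letters to use for conformer states (default
#'   `LETTERS`).
#' @return List with `alignment` (an [sa_alignment()]; columns are slots,
#'   chain by chain), `states` (latent conformer matrix), `truth` (list:
#'   `couplings`, `regime_id`, `regimes`, `slot_of_column` tibble).
#' @export
simulate_alignment <- function(spec, letters_pool = LETTERS) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$n_conformers > length(letters_pool)) {
    abort("Not enough letters in the pool for the conformer count.")
  }
  S <- .with_seed(spec$seed, .draw_states(spec))
  L <- matrix(letters_pool[S], nrow = nrow(S))
  frag_map <- tibble(
    column = seq_len(ncol(L)),
    chain = rep(LETTERS[seq_len(spec$chains)], each = spec$n_fragments),
    # slots are non-overlapping 4-residue windows: starts 1, 5, 9, ...
    first_resid = rep(4L * (seq_len(spec$n_fragments) - 1L) + 1L,
                      times = spec$chains)
  )
  aln <- sa_alignment(L, frag_map, library_name = "synthetic",
                      source = sprintf("sim seed %d", spec$seed))
  list(
    alignment = aln, states = S,
    truth = list(
      couplings = spec$couplings,
      regime_id = attr(S, "regime_id"),
      regimes = spec$regimes,
      slot_of_column = dplyr::mutate(frag_map,
        slot = rep(seq_len(spec$n_fragments), times = spec$chains))
    )
  )
}

#' Simulate a Calpha trajectory with planted fragment conformers
#'
#' Builds each chain frame-by-frame by placing, for every slot, the
#' prototype geometry of the slot's current conformer letter (rigidly
#' translated onto an extended scaffold with ~0.38 nm Calpha spacing,
#' optionally with Gaussian coordinate noise). At zero noise,
#' [encode_trajectory()] recovers the planted letters exactly at the slot
#' columns (window starts 1, 5, 9, ... of each chain).
#'
#' @param spec A [sim_spec()].
#' @param library A [fragment_library()] supplying the prototype geometries
#'   (default [default_library()]); conformer `k` of slot `s` uses letter
#'   index `((s - 1) * n_conformers + k - 1) %% n_letters + 1`.
#' @return List with `trajectory`, `planted` (frames x slots letter matrix),
#'   `states`, `truth` (as in [simulate_alignment()], plus `slot_columns`,
#'   the alignment column index of every slot after stride-1 encoding).
#' @export
simulate_trajectory <- function(spec, library = default_library()) {
  stopifnot(inherits(spec, "sim_spec"))
  nl <- length(library$letters)
  if (spec$n_conformers > nl) abort("Library too small for conformer count.")
  slot_letter <- function(slot, k) {
    library$letters[((slot - 1L) * spec$n_conformers + (k - 1L)) %% nl + 1L]
  }
  protos_centred <- lapply(library$prototypes,
                           function(p) sweep(p, 2, colMeans(p)))
  res <- .with_seed(spec$seed, {
    S <- .draw_states(spec)
    n_res <- 4L * spec$n_fragments
    n_atoms <- spec$chains * n_res
    coords <- array(NA_real_, dim = c(spec$frames, n_atoms, 3L))
    for (f in seq_len(spec$frames)) {
      for (ch in seq_len(spec$chains)) {
        for (s in seq_len(spec$n_fragments)) {
          k <- S[f, (ch - 1L) * spec$n_fragments + s]
          let <- slot_letter(s, k)
          p <- protos_centred[[let]]
          p <- sweep(p, 2, c((s - 1L) * 1.7, (ch - 1L) * 3.5, 0), `+`)
          if (spec$noise > 0) {
            p <- p + matrix(stats::rnorm(12L, sd = spec$noise), 4L, 3L)
          }
          at <- (ch - 1L) * n_res + (s - 1L) * 4L + 1:4
          coords[f, at, ] <- p
        }
      }
    }
    list(S = S, coords = coords)
  })
  S <- res$S
  n_res <- 4L * spec$n_fragments
  topology <- tibble(
    chain = rep(LETTERS[seq_len(spec$chains)], each = n_res),
    resid = rep(seq_len(n_res), times = spec$chains),
    resname = "ALA", name = "CA", mass = 12.011
  )
  traj <- trajectory(res$coords, topology)
  planted <- matrix(
    vapply(seq_len(length(S)), function(idx) {
      s <- (idx - 1L) %/% nrow(S)  # column-major index -> slot id
      slot_letter(s %% spec$n_fragments + 1L, S[idx])
    }, character(1)),
    nrow = nrow(S))
  # alignment column of slot s within its chain: stride-1 windows, start 4(s-1)+1
  per_chain_cols <- n_res - 3L
  slot_columns <- tibble(
    chain = rep(LETTERS[seq_len(spec$chains)], each = spec$n_fragments),
    slot = rep(seq_len(spec$n_fragments), times = spec$chains),
    column = as.integer(
      rep((seq_len(spec$chains) - 1L) * per_chain_cols, each = spec$n_fragments) +
        rep(4L * (seq_len(spec$n_fragments) - 1L) + 1L, times = spec$chains))
  )
  if (spec$noise > 0) {
    fid <- .encoding_fidelity(library, spec$noise, n_draws = 200L,
                              seed = spec$seed + 1L)
    if (fid < 0.99) {
      warn(sprintf(
        "Coordinate noise %g nm degrades encoding fidelity to %.1f%% (< 99%%).",
        spec$noise, 100 * fid))
    }
  }
  list(trajectory = traj, planted = planted, states = S,
       truth = list(couplings = spec$couplings,
                    regime_id = attr(S, "regime_id"),
                    regimes = spec$regimes,
                    slot_columns = slot_columns))
}

## recovery rate when re-encoding noisy copies of a calibration prototype
.encoding_fidelity <- function(library, noise, n_draws = 200L, seed = 1L) {
  .with_seed(seed, {
    hits <- vapply(seq_len(n_draws), function(d) {
      i <- ((d - 1L) %% length(library$letters)) + 1L
      p <- library$prototypes[[i]] + matrix(stats::rnorm(12L, sd = noise),
                                            4L, 3L)
      encode_chain(p, library) == library$letters[i]
    }, logical(1))
    mean(hits)
  })
}

#' Closed-form nMI of a symmetric binary coupled pair
#'
#' For two binary columns sharing their state with probability
#' `p = (1 + rho) / 2` and uniform marginals, the mutual information is
#' `ln 2 + p ln p + (1 - p) ln(1 - p)` and the joint entropy is
#' `ln 2 - p ln p - (1 - p) ln(1 - p)`; the returned value is their ratio
#' (the asymptotic nMI, without the finite-size correction).
#'
#' @param rho Coupling strength in `[0, 1]`.
#' @return List with `p`, `I`, `H`, `nmi`.
#' @export
analytic_pair_nmi <- function(rho) {
  p <- (1 + rho) / 2
  hb <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log(q) - (1 - q) * log(1 - q))
  I <- log(2) - hb(p)
  H <- log(2) + hb(p)
  list(p = p, I = I, H = H, nmi = I / H)
}
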