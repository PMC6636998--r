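#' Ensemble-averaged coupling network for one liganded state
#'
#' Integrates the substate representative matrices of all replicas of one
#' state into a single probability-weighted mean network. Each substate
#' contributes its occupancy probability divided by the number of replicas,
#' so the weights sum to 1, and the full stack of contributing matrices is
#' retained for downstream pair statistics.
#'
#' @param substate_sets One `substate_set` or a list of them (one per
#'   replica / protomer chain of the same liganded state).
#' @param state State label (e.g. `"apo"`, `"holo"`).
#' @return An object of class `ensemble_network`: list with `state`,
#'   `matrix` (weighted mean), `weights` (tibble `replica, substate,
#'   weight`), `samples` (list of contributing matrices), `fragments`,
#'   `mask`.
#' @export
ensemble_average <- function(substate_sets, state = "state") {
  if (inherits(substate_sets, "substate_set")) {
    substate_sets <- list(substate_sets)
  }
  if (length(substate_sets) == 0L) abort("Need >= 1 substate set.")
  if (!all(vapply(substate_sets, inherits, logical(1), "substate_set"))) {
    abort("All inputs must be substate_set objects.")
  }
  n_rep <- length(substate_sets)
  dims <- vapply(substate_sets,
                 function(s) nrow(s$substates$representative[[1]]), integer(1))
  if (length(unique(dims)) != 1L) {
    abort("Substate matrices have mismatched dimensions across replicas.")
  }
  samples <- list()
  weights <- list()
  acc <- 0
  for (r in seq_len(n_rep)) {
    st <- substate_sets[[r]]$substates
    for (s in seq_len(nrow(st))) {
      w <- st$probability[s] / n_rep
      acc <- acc + w * st$representative[[s]]
      samples[[length(samples) + 1L]] <- st$representative[[s]]
      weights[[length(weights) + 1L]] <-
        tibble(replica = r, substate = st$substate[s], weight = w)
    }
  }
  fragments <- substate_sets[[1]]$fragments
  structure(
    list(state = state, matrix = acc,
         weights = dplyr::bind_rows(weights), samples = samples,
         fragments = fragments %||%
           tibble(column = seq_len(dims[1]), chain = "A",
                  first_resid = seq_len(dims[1])),
         mask = NULL),
    class = "ensemble_network"
  )
}

#' @export
print.ensemble_network <- function(x, ...) {
  cat(sprintf(
    "<ensemble_network> state '%s': %d x %d fragments, %d substate sample(s)\n",
    x$state, nrow(x$matrix), ncol(x$matrix), length(x$samples)))
  invisible(x)
}

#' Difference network between two liganded-state ensembles
#'
#' Per fragment pair, the signed difference `holo - apo` of ensemble-averaged
#' nMI and the regularised log2 fold-change
#' `log2((nMI_holo + c) / (nMI_apo + c))`. The pseudocount `c` (default
#' 1e-3) keeps the ratio finite when a pair is uncoupled (nMI exactly 0) in
#' one state. Positive log2fc marks couplings that strengthen upon ligand
#' binding.
#'
#' @param apo,holo [ensemble_average()] networks on the same fragment space.
#' @param pseudocount Regularisation constant `c` (default `1e-3`).
#' @return An object of class `diff_network`: `pairs` tibble (`i, j, frag_i,
#'   frag_j, nmi_apo, nmi_holo, delta, log2fc`), `log2fc` and `delta`
#'   matrices, state labels, and the two sample stacks.
#' @export
difference_network <- function(apo, holo, pseudocount = 1e-3) {
  stopifnot(inherits(apo, "ensemble_network"),
            inherits(holo, "ensemble_network"))
  if (!all(dim(apo$matrix) == dim(holo$matrix))) {
    abort("Ensemble networks have mismatched dimensions.")
  }
  if (!identical(apo$fragments$first_resid, holo$fragments$first_resid) ||
      !identical(apo$fragments$chain, holo$fragments$chain)) {
    abort("Ensemble networks are defined on different fragment spaces.")
  }
  c0 <- pseudocount
  lfc <- log2((holo$matrix + c0) / (apo$matrix + c0))
  delta <- holo$matrix - apo$matrix
  frags <- apo$fragments
  labs <- paste0(frags$chain, frags$first_resid)
  ut <- which(upper.tri(lfc), arr.ind = TRUE)
  masked <- if (!is.null(apo$mask)) apo$mask[ut] else
    abs(frags$first_resid[ut[, 1]] - frags$first_resid[ut[, 2]]) <= 3L &
      frags$chain[ut[, 1]] == frags$chain[ut[, 2]]
  pairs <- tibble(
    i = ut[, 1], j = ut[, 2],
    frag_i = labs[ut[, 1]], frag_j = labs[ut[, 2]],
    nmi_apo = apo$matrix[ut], nmi_holo = holo$matrix[ut],
    delta = delta[ut], log2fc = lfc[ut], masked = masked
  )
  structure(
    list(pairs = pairs, log2fc = lfc, delta = delta,
         state_apo = apo$state, state_holo = holo$state,
         pseudocount = c0, fragments = frags,
         samples_apo = apo$samples, samples_holo = holo$samples),
    class = "diff_network"
  )
}

#' @export
print.diff_network <- function(x, ...) {
  cat(sprintf(
    "<diff_network> %s vs %s: %d pairs (pseudocount %g), max |log2fc| %.2f\n",
    x$state_holo, x$state_apo, nrow(x$pairs), x$pseudocount,
    max(abs(x$pairs$log2fc[!x$pairs$masked]))))
  invisible(x)
}

#' @export
tidy.diff_network <- function(x, ...) x$pairs

#' Call allosteric hub fragments from a difference network
#'
#' Per fragment pair, a two-sided Wilcoxon rank-sum test compares the
#' per-substate nMI samples of the two states (each substate representative,
#' per replica/protomer, is one observation). P-values are
#' Benjamini-Hochberg adjusted across all unmasked pairs. A pair is
#' significant when `|log2fc| >= lfc_min` and `q <= q_max` (defaults 2 and
#' 5e-4, the volcano-plot filter); passing `p_max` instead filters on the
#' raw rank-sum p-value (the protocol variant; note the exact two-sided
#' rank-sum p cannot go below `2/choose(n1+n2, n1)`, so small sample stacks
#' need `p_max`). Hub fragments are fragments incident to at least one
#' significant pair, scored by their largest `|log2fc|` among significant
#' pairs and ranked descending (ties towards the lower fragment index).
#'
#' @param diff A [difference_network()] result.
#' @param lfc_min Minimum absolute log2 fold-change (default 2).
#' @param q_max Maximum BH-adjusted q (default 5e-4). Ignored if `p_max`
#'   is given.
#' @param p_max Optional maximum raw p-value (alternative filter).
#' @param top_k Optional: keep only the `top_k` highest-ranked hubs.
#' @return An object of class `hub_table`: `pairs` tibble with `p`, `q`,
#'   `significant`; `hubs` tibble (`fragment`, `chain`, `first_resid`,
#'   `residues`, `score`, `n_significant`, `rank`); the thresholds used.
#' @export
call_hubs <- function(diff, lfc_min = 2, q_max = 5e-4, p_max = NULL,
                      top_k = NULL) {
  stopifnot(inherits(diff, "diff_network"))
  na <- length(diff$samples_apo); nh <- length(diff$samples_holo)
  if (na < 2L || nh < 2L) {
    abort(paste0(
      "Need >= 2 substate samples per state for the rank-sum test ",
      "(have ", na, " apo, ", nh, " holo). Provide more replicas or ",
      "relax substate segmentation."))
  }
  pairs <- diff$pairs
  test_pair <- function(i, j) {
    xa <- vapply(diff$samples_apo, function(m) m[i, j], numeric(1))
    xh <- vapply(diff$samples_holo, function(m) m[i, j], numeric(1))
    if (all(xa == xa[1]) && all(xh == xh[1]) && xa[1] == xh[1]) return(1)
    suppressWarnings(wilcox.test(xh, xa, exact = TRUE)$p.value)
  }
  p <- rep(NA_real_, nrow(pairs))
  un <- which(!pairs$masked)
  p[un] <- vapply(un, function(k) test_pair(pairs$i[k], pairs$j[k]),
                  numeric(1))
  q <- rep(NA_real_, nrow(pairs))
  q[un] <- p.adjust(p[un], method = "BH")
  pairs$p <- p
  pairs$q <- q
  crit <- if (!is.null(p_max)) !is.na(p) & p <= p_max else !is.na(q) & q <= q_max
  pairs$significant <- !pairs$masked & abs(pairs$log2fc) >= lfc_min & crit
  sig <- pairs[pairs$significant, ]
  frags <- diff$fragments
  hub_rows <- lapply(seq_len(nrow(frags)), function(f) {
    inc <- sig[sig$i == f | sig$j == f, ]
    if (nrow(inc) == 0L) return(NULL)
    tibble(fragment = f, chain = frags$chain[f],
           first_resid = frags$first_resid[f],
           residues = paste0(frags$first_resid[f], "-",
                             frags$first_resid[f] + 3L),
           score = max(abs(inc$log2fc)),
           n_significant = nrow(inc))
  })
  hubs <- dplyr::bind_rows(hub_rows)
  if (nrow(hubs) > 0L) {
    ord <- order(-hubs$score, hubs$fragment)
    hubs <- hubs[ord, ]
    hubs$rank <- seq_len(nrow(hubs))
    if (!is.null(top_k)) hubs <- head(hubs, top_k)
  } else {
    hubs <- tibble(fragment = integer(), chain = character(),
                   first_resid = integer(), residues = character(),
                   score = numeric(), n_significant = integer(),
                   rank = integer())
  }
  structure(
    list(pairs = pairs, hubs = hubs, lfc_min = lfc_min, q_max = q_max,
         p_max = p_max, state_apo = diff$state_apo,
         state_holo = diff$state_holo, fragments = frags),
    class = "hub_table"
  )
}

#' @export
print.hub_table <- function(x, ...) {
  cat(sprintf(
    "<hub_table> %s vs %s: %d/%d pairs significant (|log2fc| >= %g, %s), %d hub fragment(s)\n",
    x$state_holo, x$state_apo, sum(x$pairs$significant),
    sum(!x$pairs$masked), x$lfc_min,
    if (!is.null(x$p_max)) paste0("p <= ", x$p_max)
    else paste0("q <= ", x$q_max),
    nrow(x$hubs)))
  if (nrow(x$hubs)) print(head(x$hubs, 10))
  invisible(x)
}

#' @export
tidy.hub_table <- function(x, ...) x$pairs

#' @export
glance.hub_table <- function(x, ...) {
  tibble(n_pairs = sum(!x$pairs$masked),
         n_significant = sum(x$pairs$significant),
         n_hubs = nrow(x$hubs),
         lfc_min = x$lfc_min,
         q_max = if (is.null(x$p_max)) x$q_max else NA_real_,
         p_max = x$p_max %||% NA_real_,
         top_score = if (nrow(x$hubs)) max(x$hubs$score) else NA_real_)
}

#' Suggest tolerated substitutions at hub positions from an MSA
#'
#' Maps target-sequence positions to columns of a protein multiple sequence
#' alignment (skipping target gaps) and reports, per position, the residues
#' other than the wild type whose column frequency is at least `min_freq` —
#' candidate conservative mutations observed across orthologues.
#'
#' @param msa FASTA path or a named character vector of aligned sequences
#'   (equal lengths, `-` for gaps).
#' @param target_id Name of the target sequence in the MSA.
#' @param positions 1-based positions in the ungapped target sequence.
#' @param min_freq Minimum column frequency (default 0.05).
#' @return Tibble with columns `position`, `column`, `wt`, `residue`,
#'   `freq`, one row per tolerated residue (positions mapping to all-gap
#'   columns yield a warning and no rows).
#' @export
suggest_substitutions <- function(msa, target_id, positions,
                                  min_freq = 0.05) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::readAAStringSet(msa)
      seqs <- as.character(ss)
    } else {
      lines <- readLines(msa, warn = FALSE)
      hdr <- grepl("^>", lines)
      idx <- cumsum(hdr)
      seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0,
                     character(1), collapse = "")
      names(seqs) <- sub("^>(\\S+).*$", "\\1", lines[hdr])
    }
  } else {
    seqs <- msa
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!target_id %in% names(seqs)) {
    abort(paste0("Target id '", target_id, "' not found in MSA."))
  }
  if (length(unique(nchar(seqs))) != 1L) {
    abort("MSA sequences must have equal aligned lengths.")
  }
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  target <- M[match(target_id, names(seqs)), ]
  not_gap <- which(!target %in% c("-", "."))
  out <- list()
  for (pos in positions) {
    if (pos < 1L || pos > length(not_gap)) {
      abort(sprintf("Position %d outside target length %d.", pos,
                    length(not_gap)))
    }
    col <- not_gap[pos]
    letters_col <- M[, col]
    wt <- target[col]
    keep <- !letters_col %in% c("-", ".", "X")
    if (!any(keep)) {
      warn(sprintf("Position %d maps to an all-gap column %d.", pos, col))
      next
    }
    freq <- table(letters_col[keep]) / nrow(M)  # freq over all sequences
    freq <- freq[names(freq) != wt & freq >= min_freq]
    if (length(freq)) {
      out[[length(out) + 1L]] <- tibble(
        position = pos, column = col, wt = wt,
        residue = names(freq), freq = as.numeric(freq))
    } else {
      out[[length(out) + 1L]] <- tibble(
        position = pos, column = col, wt = wt,
        residue = character(0), freq = numeric(0))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(position = integer(), column = integer(),
                  wt = character(), residue = character(), freq = numeric())
  }
  dplyr::arrange(res, .data$position, dplyr::desc(.data$freq))
}

#' Allosteric coupling coefficient Q
#'
#' `Q = K_ia / K_ia_x`, the ratio of the substrate
#' dissociation/Michaelis constant in the absence over the presence of an
#' allosteric effector. `Q > 1` (log10 Q > 0) indicates positive coupling
#' (activation: the effector increases substrate affinity); `Q < 1`
#' indicates negative coupling (inhibition).
#'
#' @param k_ia Substrate constant without effector (e.g. mM); vectorised.
#' @param k_ia_x Substrate constant with effector, same units.
#' @return Tibble with columns `k_ia`, `k_ia_x`, `Q`, `log10Q`, `coupling`
#'   (`"activation"` / `"inhibition"` / `"none"`).
#' @examples
#' coupling_q(1.22, c(FBP = 0.23, Phe = 7.08))
#' @export
coupling_q <- function(k_ia, k_ia_x) {
  if (any(!is.finite(k_ia)) || any(!is.finite(k_ia_x)) ||
      any(k_ia <= 0) || any(k_ia_x <= 0)) {
    abort("Both constants must be positive and finite.")
  }
  Q <- k_ia / k_ia_x
  tibble(
    effector = names(k_ia_x) %||% rep(NA_character_, length(Q)),
    k_ia = rep_len(k_ia, length(Q)), k_ia_x = as.numeric(k_ia_x),
    Q = as.numeric(Q), log10Q = log10(as.numeric(Q)),
    coupling = dplyr::case_when(Q > 1 ~ "activation",
                                Q < 1 ~ "inhibition",
                                TRUE ~ "none")
  )
}
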