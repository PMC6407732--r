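#' Shannon entropy of a dwell-location distribution
#'
#' Entropy in bits of the distribution of dwells over the search elements,
#' `H = -sum p_i log2 p_i` with `0 log 0 = 0`, where `p_i` is the proportion
#' of all dwells (pooled over a condition's trials) that landed on element
#' `i`.  Maximal (`log2(n)`) when dwells are spread evenly, 0 when a single
#' element receives them all.
#'
#' @param counts Non-negative dwell counts per element.
#' @return Entropy in bits.
#' @examples
#' dwell_distribution_entropy(rep(4, 25)) # log2(25)
#' @export
dwell_distribution_entropy <- function(counts) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("undefined metric: all counts are zero",
                       call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Entropy of inter-element transitions
#'
#' Two variants of the scanpath transition entropy computed from a square
#' matrix of transition counts (`[i, j]` = transitions from element `i` to
#' element `j`, pooled over trials; the diagonal must be zero since a
#' transition always changes element):
#'
#' * conditional: `-sum_i p(i) sum_j p(j|i) log2 p(j|i)`, the expected
#'   unpredictability of the next element given the current one, with
#'   `p(i)` the marginal distribution of transition origins.  Maximum
#'   `log2(n - 1)` bits.
#' * joint: `-sum_{i != j} p(i, j) log2 p(i, j)`, the unpredictability of
#'   the ordered origin-destination pair.  Maximum `log2(n * (n - 1))`
#'   bits - 9.23 bits for a 5x5 array, the value quoted as the theoretical
#'   maximum for fully random scanning.
#'
#' Both are reported because the two variants answer slightly different
#' questions and published maxima for this measure correspond to the joint
#' form.  The identity `joint = conditional + entropy(origin marginal)`
#' makes `joint >= conditional` always.
#'
#' @param counts A square numeric matrix of non-negative transition counts
#'   with zero diagonal.
#' @return A one-row tibble: `h_conditional`, `h_joint`, `n_transitions`.
#' @examples
#' m <- matrix(1, 25, 25); diag(m) <- 0
#' transition_entropy(m) # joint = log2(600) = 9.23 bits
#' @export
transition_entropy <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    stop("invalid matrix: `counts` must be square", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("invalid matrix: counts must be finite and non-negative",
         call. = FALSE)
  }
  if (any(diag(counts) != 0)) {
    stop("invalid matrix: diagonal (self-transitions) must be zero",
         call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("undefined metric: no transitions", call. = FALSE)

  row_tot <- rowSums(counts)
  p_origin <- row_tot / total
  h_rows <- vapply(seq_len(nrow(counts)), function(i) {
    if (row_tot[i] == 0) return(0)
    p <- counts[i, ]
    p <- p[p > 0] / row_tot[i]
    -sum(p * log2(p))
  }, numeric(1))
  h_conditional <- sum(p_origin * h_rows)

  pj <- counts[counts > 0] / total
  h_joint <- -sum(pj * log2(pj))

  tibble::tibble(h_conditional = h_conditional, h_joint = h_joint,
                 n_transitions = total)
}

#' Pool dwell sequences into per-element counts
#'
#' @param dwell_seqs A list of integer vectors of visited cell ids (one per
#'   trial), or a single vector.
#' @param n_elements Number of elements in the array.
#' @return An integer vector of length `n_elements` of dwell counts.
#' @export
dwell_counts <- function(dwell_seqs, n_elements = 25) {
  if (!is.list(dwell_seqs)) dwell_seqs <- list(dwell_seqs)
  all_h <- unlist(dwell_seqs, use.names = FALSE)
  tabulate(all_h + 1L, nbins = n_elements)
}

#' Pool dwell sequences into a transition-count matrix
#'
#' Transitions are consecutive entries within each sequence; sequences never
#' contribute a transition across trial boundaries.  Consecutive repeats
#' (possible when an outside fixation split a dwell) are not transitions and
#' are skipped.
#'
#' @inheritParams dwell_counts
#' @return An `n_elements` x `n_elements` count matrix with zero diagonal.
#' @export
transition_counts <- function(dwell_seqs, n_elements = 25) {
  if (!is.list(dwell_seqs)) dwell_seqs <- list(dwell_seqs)
  m <- matrix(0, n_elements, n_elements)
  for (s in dwell_seqs) {
    if (length(s) < 2) next
    from <- s[-length(s)]
    to <- s[-1]
    keep <- from != to
    for (k in which(keep)) {
      m[from[k] + 1L, to[k] + 1L] <- m[from[k] + 1L, to[k] + 1L] + 1
    }
  }
  m
}

#' Entropy summary of a set of dwell sequences
#'
#' Convenience wrapper computing both entropy measures for one searcher in
#' one condition from the per-trial dwell sequences.
#'
#' @inheritParams dwell_counts
#' @return A one-row tibble: `h_dwell`, `h_transition_conditional`,
#'   `h_transition_joint`, `n_dwells`, `n_transitions`.
#' @export
scan_entropy <- function(dwell_seqs, n_elements = 25) {
  dc <- dwell_counts(dwell_seqs, n_elements)
  tc <- transition_counts(dwell_seqs, n_elements)
  te <- if (sum(tc) > 0) {
    transition_entropy(tc)
  } else {
    tibble::tibble(h_conditional = NA_real_, h_joint = NA_real_,
                   n_transitions = 0)
  }
  tibble::tibble(
    h_dwell = dwell_distribution_entropy(dc),
    h_transition_conditional = te$h_conditional,
    h_transition_joint = te$h_joint,
    n_dwells = sum(dc),
    n_transitions = te$n_transitions
  )
}
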