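#' Degree- and sign-preserving network permutation (edge swapping)
#'
#' Randomizes a signed directed network by repeated edge swaps: two edges
#' `a -> b` and `c -> d` are rewired to `a -> d` and `c -> b`. Polarity and
#' relation label travel with the *source* endpoint, so every node keeps
#' its exact out-degree, in-degree, and signed out-degree, and the global
#' polarity multiset is untouched. A proposed swap is rejected (and another
#' attempted) when it would create a self-loop or duplicate an existing
#' `(from, to, polarity)` edge. When node modalities are present, swaps are
#' only proposed within a relation layer (edges with the same
#' source-modality/target-modality pair), preserving the multimodal
#' layering of drug-protein-disease networks.
#'
#' @param net A [signed_network()].
#' @param n_swaps Number of swap attempts; the default `10 * |E|` follows
#'   common practice for degree-preserving randomization.
#' @param seed Integer seed; the permutation is deterministic given the
#'   seed and does not disturb the session RNG.
#' @return A permuted [signed_network()] with identical nodes, degree
#'   sequences and polarity counts.
#' @examples
#' net <- generate_network(synthetic_spec(seed = 1))
#' perm <- xswap_permute(net, seed = 2)
#' identical(network_summary(net)$polarities, network_summary(perm)$polarities)
#' @export
xswap_permute <- function(net, n_swaps = 10 * nrow(net$edges), seed = 1) {
  stopifnot(inherits(net, "signed_network"), n_swaps >= 0)
  edges <- net$edges
  m <- nrow(edges)
  if (m < 2 || n_swaps == 0) {
    return(net)
  }
  modality <- stats::setNames(net$nodes$modality, net$nodes$id)
  layer <- paste(modality[edges$from], modality[edges$to], sep = "->")
  groups <- split(seq_len(m), layer)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (length(groups) == 0) {
    return(net)
  }
  from <- edges$from
  to <- edges$to
  pol <- edges$polarity
  key <- function(f, t, p) paste(f, t, p, sep = "\r")
  existing <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(key(from[i], to[i], pol[i]), TRUE, existing)
  gsizes <- vapply(groups, length, 1L)
  withr::with_seed(seed, {
    # pick the layer proportionally to its edge count, then two edges in it
    gpick <- sample.int(length(groups), n_swaps,
      replace = TRUE, prob = gsizes
    )
    for (a in seq_len(n_swaps)) {
      grp <- groups[[gpick[a]]]
      ij <- grp[sample.int(length(grp), 2)]
      i <- ij[1]
      j <- ij[2]
      # proposal: i keeps its source, polarity, relation; targets swap
      nt_i <- to[j]
      nt_j <- to[i]
      if (from[i] == nt_i || from[j] == nt_j) next # self-loop
      k1 <- key(from[i], nt_i, pol[i])
      k2 <- key(from[j], nt_j, pol[j])
      if (exists(k1, existing, inherits = FALSE) ||
        exists(k2, existing, inherits = FALSE) || k1 == k2) {
        next # duplicate edge
      }
      rm(list = c(
        key(from[i], to[i], pol[i]),
        key(from[j], to[j], pol[j])
      ), envir = existing)
      to[i] <- nt_i
      to[j] <- nt_j
      assign(k1, TRUE, existing)
      assign(k2, TRUE, existing)
    }
  })
  out <- net
  out$edges$to <- to
  out
}
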