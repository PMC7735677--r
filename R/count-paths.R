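#' Count activatory and inhibitory causal paths between two nodes
#'
#' The core operation of the package. The *effect* of a directed path is the
#' product of its edge polarities: a path is activatory when the product is
#' `+1` and inhibitory when it is `-1`. `count_paths()` counts, for a source
#' `from` and a target `to`, the paths of length `1..lmax` in each class.
#'
#' Two variants are provided:
#' * `variant = "all"` counts **target-absorbing walks**: vertices other
#'   than the target may repeat (cycles are traversed, up to the length
#'   budget), but a walk terminates at its *first* arrival at the target —
#'   walks through the target and back are not counted. This variant runs by
#'   memoized dynamic programming on states `(node, remaining length)`: the
#'   signed count of walks from `u` to the target within `k` steps is the
#'   polarity-adjusted sum over out-edges `u -> v` of the counts from `v`
#'   within `k - 1` steps (an inhibitory edge swaps the activatory and
#'   inhibitory suffix counts, because path effects compose by sign
#'   multiplication). Each state is evaluated at most once, so at most
#'   `|V| * (lmax + 1)` states are ever touched, giving `O(lmax * |V|)`
#'   state complexity regardless of how many walks are counted.
#' * `variant = "simple"` counts **simple paths** (all vertices distinct)
#'   by depth-first search with an explicit visited set, pruned by the
#'   remaining-length budget and by a reverse breadth-first-search table of
#'   distances to the target (a branch is abandoned as soon as the target is
#'   provably out of reach). No cross-branch memoization is used — cached
#'   counts would be invalid under differing visited sets.
#'
#' The degenerate query `from == to` returns one activatory path (the empty
#' product is `+1`) for either variant; applications that require at least
#' one intermediate node should use `lmax >= 2` and distinct endpoints.
#'
#' Counts are exact integers stored as doubles (exact up to 2^53; a warning
#' is emitted in the astronomically dense regime beyond that).
#'
#' @param net A [signed_network()].
#' @param from,to Node ids (single strings).
#' @param lmax Maximum path length in edges, `>= 1`.
#' @param variant `"all"` (walks, cycles allowed) or `"simple"`.
#' @return A one-row tibble with columns `from`, `to`, `lmax`, `variant`,
#'   `activatory`, `inhibitory`, `total`. The attribute `"states"` carries
#'   the number of distinct dynamic-programming states evaluated (for the
#'   `"all"` variant), and `"by_length"` a per-exact-length breakdown
#'   tibble (`length`, `activatory`, `inhibitory`).
#' @examples
#' net <- signed_network(data.frame(
#'   from = c("s", "a", "s", "b"), to = c("a", "t", "b", "t"),
#'   polarity = c(1, 1, 1, -1)
#' ))
#' count_paths(net, "s", "t", lmax = 2)
#' @export
count_paths <- function(net, from, to, lmax, variant = c("all", "simple")) {
  variant <- match.arg(variant)
  stopifnot(inherits(net, "signed_network"), length(from) == 1, length(to) == 1)
  if (lmax < 1) stop("`lmax` must be >= 1", call. = FALSE)
  lmax <- as.integer(lmax)
  idx <- network_index(net)
  s_i <- match(from, idx$ids)
  t_i <- match(to, idx$ids)
  if (is.na(s_i)) stop("unknown node id: ", from, call. = FALSE)
  if (is.na(t_i)) stop("unknown node id: ", to, call. = FALSE)

  res <- if (variant == "all") {
    count_walks_dp(idx, s_i, t_i, lmax)
  } else {
    count_simple_dfs(idx, s_i, t_i, lmax)
  }
  act_by_len <- res$act_by_len
  inh_by_len <- res$inh_by_len
  activatory <- sum(act_by_len)
  inhibitory <- sum(inh_by_len)
  if (from == to) { # empty path, absorbing at length 0
    activatory <- activatory + 1
  }
  if (activatory + inhibitory > 2^53) {
    warning("path counts exceed 2^53; integer exactness is no longer ",
      "guaranteed",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    from = from, to = to, lmax = lmax, variant = variant,
    activatory = activatory, inhibitory = inhibitory,
    total = activatory + inhibitory
  )
  attr(out, "states") <- res$states
  attr(out, "by_length") <- tibble::tibble(
    length = seq_len(lmax),
    activatory = act_by_len,
    inhibitory = inh_by_len
  )
  out
}

# internal: dynamic programming over (node, exact length) states, evaluated
# bottom-up so each state is touched exactly once (the iterative equivalent
# of top-down memoization). P_k[u] / N_k[u] hold the number of
# positive-/negative-effect target-absorbing walks from u to t of length
# exactly k; the absorbing base case is the single zero-length walk sitting
# at t, and t is never expanded, so walks terminate at first arrival.
count_walks_dp <- function(idx, s_i, t_i, lmax) {
  n <- length(idx$ids)
  adj_to <- idx$adj_to
  adj_sign <- idx$adj_sign
  pos_prev <- numeric(n) # exact length k - 1
  neg_prev <- numeric(n)
  pos_prev[t_i] <- 1 # absorbing base case: the length-0 walk at the target
  act_by_len <- numeric(lmax)
  inh_by_len <- numeric(lmax)
  states <- 0L
  # only nodes that can reach t can ever hold a nonzero count
  active <- which(is.finite(distance_to_target(idx, t_i)))
  active <- active[active != t_i]
  for (k in seq_len(lmax)) {
    pos_cur <- numeric(n)
    neg_cur <- numeric(n)
    touched <- pos_prev != 0 | neg_prev != 0
    for (u in active) {
      tos <- adj_to[[u]]
      if (is.null(tos)) next
      states <- states + 1L
      keep <- touched[tos]
      if (!any(keep)) next
      tos <- tos[keep]
      sg <- adj_sign[[u]][keep]
      up <- sg > 0
      # an inhibitory edge swaps the suffix's activatory/inhibitory counts
      pos_cur[u] <- sum(pos_prev[tos[up]]) + sum(neg_prev[tos[!up]])
      neg_cur[u] <- sum(neg_prev[tos[up]]) + sum(pos_prev[tos[!up]])
    }
    act_by_len[k] <- pos_cur[s_i]
    inh_by_len[k] <- neg_cur[s_i]
    pos_prev <- pos_cur # pos_cur[t_i] stays 0: no length-k walk sits at t
    neg_prev <- neg_cur
  }
  list(act_by_len = act_by_len, inh_by_len = inh_by_len, states = states)
}

# internal: simple-path DFS with visited set, length budget, and
# distance-to-target pruning
count_simple_dfs <- function(idx, s_i, t_i, lmax) {
  n <- length(idx$ids)
  adj_to <- idx$adj_to
  adj_sign <- idx$adj_sign
  dist_t <- distance_to_target(idx, t_i)
  act_by_len <- numeric(lmax)
  inh_by_len <- numeric(lmax)
  if (s_i == t_i) {
    return(list(act_by_len = act_by_len, inh_by_len = inh_by_len, states = 0L))
  }
  visited <- logical(n)
  depth0 <- lmax
  dfs <- function(u, remaining, sign) {
    visited[u] <<- TRUE
    tos <- adj_to[[u]]
    if (!is.null(tos)) {
      sg <- adj_sign[[u]]
      for (j in seq_along(tos)) {
        v <- tos[j]
        s2 <- sign * sg[j]
        if (v == t_i) {
          len <- depth0 - remaining + 1L
          if (s2 > 0) {
            act_by_len[len] <<- act_by_len[len] + 1
          } else {
            inh_by_len[len] <<- inh_by_len[len] + 1
          }
        } else if (remaining > 1L && !visited[v] &&
          dist_t[v] <= remaining - 1L) {
          dfs(v, remaining - 1L, s2)
        }
      }
    }
    visited[u] <<- FALSE
  }
  if (is.finite(dist_t[s_i]) && dist_t[s_i] <= lmax) dfs(s_i, lmax, 1)
  list(act_by_len = act_by_len, inh_by_len = inh_by_len, states = NA_integer_)
}
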