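# Independent brute-force oracles for the counting engine. These enumerate
# paths explicitly (storing the walk under construction) and never share
# code with the package's dynamic-programming / pruned-DFS implementations.

# adjacency view straight off the edge tibble
oracle_adj <- function(net) {
  split(
    data.frame(to = net$edges$to, sign = net$edges$polarity,
      stringsAsFactors = FALSE),
    net$edges$from
  )
}

# target-absorbing walks: expand every out-edge, stop on first arrival at
# the target; vertices may repeat
oracle_count_walks <- function(net, s, t, lmax) {
  adj <- oracle_adj(net)
  act <- 0
  inh <- 0
  recurse <- function(u, remaining, sign) {
    out <- adj[[u]]
    if (is.null(out) || remaining == 0) return(invisible())
    for (i in seq_len(nrow(out))) {
      v <- out$to[i]
      s2 <- sign * out$sign[i]
      if (v == t) {
        if (s2 > 0) act <<- act + 1 else inh <<- inh + 1
      } else if (remaining > 1) {
        recurse(v, remaining - 1, s2)
      }
    }
  }
  if (s == t) act <- act + 1 else recurse(s, lmax, 1)
  c(activatory = act, inhibitory = inh)
}

# simple paths: all vertices distinct, no pruning beyond the length budget
oracle_count_simple <- function(net, s, t, lmax) {
  adj <- oracle_adj(net)
  act <- 0
  inh <- 0
  recurse <- function(u, remaining, sign, seen) {
    out <- adj[[u]]
    if (is.null(out) || remaining == 0) return(invisible())
    for (i in seq_len(nrow(out))) {
      v <- out$to[i]
      s2 <- sign * out$sign[i]
      if (v == t) {
        if (s2 > 0) act <<- act + 1 else inh <<- inh + 1
      } else if (remaining > 1 && !v %in% seen) {
        recurse(v, remaining - 1, s2, c(seen, v))
      }
    }
  }
  if (s == t) act <- act + 1 else recurse(s, lmax, 1, s)
  c(activatory = act, inhibitory = inh)
}

# seeded Erdos-Renyi signed digraph on nodes n1..nn
random_signed_network <- function(n, p = 0.3, p_inh = 0.5, seed = 1,
                                  dag = FALSE) {
  withr::with_seed(seed, {
    ids <- paste0("n", seq_len(n))
    grid <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
    grid <- grid[grid$from != grid$to, ]
    if (dag) {
      grid <- grid[match(grid$from, ids) < match(grid$to, ids), ]
    }
    keep <- stats::runif(nrow(grid)) < p
    grid <- grid[keep, , drop = FALSE]
    grid$polarity <- ifelse(stats::runif(nrow(grid)) < p_inh, -1, 1)
    signed_network(grid, nodes = data.frame(id = ids))
  })
}

# flip the polarity of every edge
negate_network <- function(net) {
  e <- net$edges
  e$polarity <- -e$polarity
  signed_network(e, net$nodes)
}

# flip only the edges entering `target`: every source->target path contains
# exactly one such edge, so every path effect flips sign exactly once
negate_into_target <- function(net, target) {
  e <- net$edges
  e$polarity <- ifelse(e$to == target, -e$polarity, e$polarity)
  signed_network(e, net$nodes)
}
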