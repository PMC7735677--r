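#' Build a signed directed network
#'
#' The central data structure of the package: a directed graph whose edges
#' each carry a polarity, `+1` for an activatory relationship and `-1` for an
#' inhibitory one. Nodes optionally carry a *modality* (`drug`, `protein`,
#' `indication`, `phenotype`, or `other`) describing which layer of a
#' multimodal biological network they belong to; the path-counting engine
#' never requires modalities, they are metadata used by the generator, the
#' permutation null, and summaries.
#'
#' Node identifiers are opaque strings and are preserved verbatim (a
#' namespaced id such as `"drugbank:DB00001"` is never parsed). Duplicate
#' edges with identical `(from, to, polarity)` are collapsed to a single edge
#' (with a warning); a pair of parallel edges with *opposite* polarity is
#' kept — context-dependent regulation where the same interaction can
#' activate or inhibit is biologically meaningful, and the counting engine
#' treats the two edges as distinct.
#'
#' @param edges A data frame with columns `from`, `to`, `polarity`
#'   (each `+1` or `-1`) and optionally `relation` (free-text label,
#'   defaults to `"activation"`/`"inhibition"` according to polarity).
#' @param nodes Optional data frame with columns `id` and optionally
#'   `modality`. Nodes appearing in `edges` but not listed here are added
#'   with modality `"other"`; listing extra ids creates isolated nodes.
#' @return An object of class `signed_network`: a list with tibbles `nodes`
#'   (`id`, `modality`) and `edges` (`from`, `to`, `polarity`, `relation`).
#' @examples
#' net <- signed_network(data.frame(
#'   from = c("D1", "P1"), to = c("P1", "Dis1"), polarity = c(1, -1)
#' ))
#' net
#' @export
signed_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(
      from = character(), to = character(),
      polarity = numeric(), relation = character()
    )
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "polarity") %in% names(edges)))
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$polarity <- as.numeric(edges$polarity)
    if (!all(edges$polarity %in% c(-1, 1))) {
      stop("every edge polarity must be exactly +1 or -1", call. = FALSE)
    }
    if (!"relation" %in% names(edges)) {
      edges$relation <- ifelse(edges$polarity > 0, "activation", "inhibition")
    }
    edges <- edges[, c("from", "to", "polarity", "relation")]
    key <- paste(edges$from, edges$to, edges$polarity, sep = "\r")
    if (anyDuplicated(key)) {
      warning("collapsing duplicate edges with identical (from, to, polarity)",
        call. = FALSE
      )
      edges <- edges[!duplicated(key), ]
    }
  } else {
    edges <- tibble::tibble(
      from = character(), to = character(),
      polarity = numeric(), relation = character()
    )
  }

  ids <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- tibble::tibble(id = ids, modality = rep("other", length(ids)))
  } else {
    nodes <- tibble::as_tibble(nodes)
    stopifnot("id" %in% names(nodes))
    nodes$id <- as.character(nodes$id)
    if (!"modality" %in% names(nodes)) nodes$modality <- "other"
    nodes$modality <- as.character(nodes$modality)
    if (anyDuplicated(nodes$id)) {
      stop("duplicate node ids in `nodes`", call. = FALSE)
    }
    missing <- setdiff(ids, nodes$id)
    if (length(missing) > 0) {
      nodes <- dplyr::bind_rows(
        nodes[, c("id", "modality")],
        tibble::tibble(id = missing, modality = "other")
      )
    } else {
      nodes <- nodes[, c("id", "modality")]
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(
    "<signed_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
    " signed directed edges\n",
    sep = ""
  )
  pol <- table(factor(x$edges$polarity, levels = c(1, -1)))
  cat("  polarity: +1 x ", pol[["1"]], ", -1 x ", pol[["-1"]], "\n", sep = "")
  mod <- table(x$nodes$modality)
  if (length(mod) > 0) {
    cat(
      "  modality: ",
      paste(names(mod), unname(mod), sep = ":", collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Summarize a signed network by modality and polarity
#'
#' @param net A [signed_network()].
#' @return A list of two tibbles: `modalities` (modality, n, summing to the
#'   node count) and `polarities` (polarity, n, summing to the edge count).
#' @examples
#' net <- signed_network(data.frame(from = "a", to = "b", polarity = 1))
#' network_summary(net)
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  modalities <- net$nodes |>
    dplyr::count(.data$modality, name = "n") |>
    dplyr::arrange(.data$modality)
  polarities <- tibble::tibble(
    polarity = c(1, -1),
    n = c(sum(net$edges$polarity == 1), sum(net$edges$polarity == -1))
  )
  list(modalities = modalities, polarities = polarities)
}

# internal: consistent node-index adjacency view used by the counting engine
network_index <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  from_i <- match(net$edges$from, ids)
  to_i <- match(net$edges$to, ids)
  adj_to <- vector("list", n)
  adj_sign <- vector("list", n)
  if (n > 0) {
    ord <- order(from_i)
    f <- from_i[ord]
    t <- to_i[ord]
    s <- net$edges$polarity[ord]
    if (length(f) > 0) {
      starts <- c(1, which(diff(f) > 0) + 1)
      ends <- c(starts[-1] - 1, length(f))
      for (j in seq_along(starts)) {
        u <- f[starts[j]]
        adj_to[[u]] <- t[starts[j]:ends[j]]
        adj_sign[[u]] <- s[starts[j]:ends[j]]
      }
    }
  }
  # reverse adjacency (unsigned), for BFS distance-to-target pruning
  radj <- vector("list", n)
  if (nrow(net$edges) > 0) {
    ord <- order(to_i)
    f <- from_i[ord]
    t <- to_i[ord]
    starts <- c(1, which(diff(t) > 0) + 1)
    ends <- c(starts[-1] - 1, length(t))
    for (j in seq_along(starts)) {
      u <- t[starts[j]]
      radj[[u]] <- unique(f[starts[j]:ends[j]])
    }
  }
  list(ids = ids, adj_to = adj_to, adj_sign = adj_sign, radj = radj)
}

# internal: BFS distances to `target` following edges backwards
distance_to_target <- function(idx, target_i) {
  n <- length(idx$ids)
  dist <- rep(Inf, n)
  dist[target_i] <- 0
  frontier <- target_i
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(idx$radj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# internal: structural equality on (node set, edge multiset); used by IO
# round-trip tests and exported for convenience
#' Compare two signed networks structurally
#'
#' Two networks are considered equal when they have the same node id set and
#' the same multiset of `(from, to, polarity)` edges. Relation labels and
#' modalities are compared only if `strict = TRUE`.
#'
#' @param a,b [signed_network()] objects.
#' @param strict Also compare modalities and relation labels.
#' @return `TRUE` or `FALSE`.
#' @export
network_equal <- function(a, b, strict = FALSE) {
  if (!setequal(a$nodes$id, b$nodes$id)) {
    return(FALSE)
  }
  ka <- sort(paste(a$edges$from, a$edges$to, a$edges$polarity, sep = "\r"))
  kb <- sort(paste(b$edges$from, b$edges$to, b$edges$polarity, sep = "\r"))
  if (!identical(ka, kb)) {
    return(FALSE)
  }
  if (strict) {
    ma <- a$nodes[order(a$nodes$id), ]
    mb <- b$nodes[order(b$nodes$id), ]
    if (!identical(ma$modality, mb$modality)) {
      return(FALSE)
    }
    ra <- sort(paste(a$edges$from, a$edges$to, a$edges$polarity,
      a$edges$relation,
      sep = "\r"
    ))
    rb <- sort(paste(b$edges$from, b$edges$to, b$edges$polarity,
      b$edges$relation,
      sep = "\r"
    ))
    if (!identical(ra, rb)) {
      return(FALSE)
    }
  }
  TRUE
}
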