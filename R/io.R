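#' Read a signed network from a standard network file
#'
#' Supported formats:
#' * `"graphml"` — parsed with igraph; edge polarity is taken from an
#'   integer edge attribute `polarity` when present, otherwise inferred from
#'   the edge attribute `relation` through `vocab`. A vertex attribute
#'   `modality` is honoured.
#' * `"nodelink"` — the common node-link JSON layout
#'   `{"directed": true, "nodes": [{"id": ...}], "links": [{"source": ...,
#'   "target": ...}]}`, with `polarity`/`relation` on links and `modality`
#'   on nodes.
#' * `"edgelist"` — tab-separated `source<TAB>relation<TAB>target`, UTF-8,
#'   no header by default (`header = TRUE` skips one line); polarity is
#'   inferred from the relation column through `vocab`. Isolated nodes
#'   cannot be represented in this dialect.
#'
#' @param path File path.
#' @param format One of `"graphml"`, `"nodelink"`, `"edgelist"`.
#' @param vocab A [polarity_vocabulary()] used to sign relation labels that
#'   carry no explicit polarity.
#' @param header Edge-list only: skip a single header line.
#' @return A [signed_network()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("D1\tactivation\tP1", "P1\tinhibition\tP2"), f)
#' read_network(f, "edgelist")
#' @export
read_network <- function(path, format = c("graphml", "nodelink", "edgelist"),
                         vocab = default_vocabulary(), header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    graphml = read_graphml(path, vocab),
    nodelink = read_nodelink(path, vocab),
    edgelist = read_edgelist(path, vocab, header)
  )
}

#' Write a signed network to a standard network file
#'
#' Inverse of [read_network()]: reading a written file reproduces the
#' network's node set and `(from, to, polarity)` edge multiset exactly.
#' The edge-list dialect stores edges only, so isolated nodes are dropped
#' (with a warning); GraphML and node-link preserve them.
#'
#' @param net A [signed_network()].
#' @param path Output file path.
#' @param format One of `"graphml"`, `"nodelink"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path,
                          format = c("graphml", "nodelink", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "signed_network"))
  switch(format,
    graphml = write_graphml(net, path),
    nodelink = write_nodelink(net, path),
    edgelist = write_edgelist(net, path)
  )
  invisible(path)
}

read_edgelist <- function(path, vocab, header) {
  tab <- readr::read_tsv(path,
    col_names = c("from", "relation", "to"), col_types = "ccc",
    skip = if (header) 1 else 0, progress = FALSE
  )
  if (nrow(tab) == 0) {
    return(signed_network())
  }
  tab$polarity <- apply_vocabulary(tab$relation, vocab)
  signed_network(tab[, c("from", "to", "polarity", "relation")])
}

write_edgelist <- function(net, path) {
  iso <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
  if (length(iso) > 0) {
    warning(
      "edge-list format cannot represent ", length(iso),
      " isolated node(s); dropped",
      call. = FALSE
    )
  }
  readr::write_tsv(net$edges[, c("from", "relation", "to")], path,
    col_names = FALSE, progress = FALSE
  )
}

read_nodelink <- function(path, vocab) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  links <- obj$links
  nodes <- if (is.null(nodes) || length(nodes) == 0) {
    NULL
  } else {
    tibble::tibble(
      id = as.character(nodes$id),
      modality = if (!is.null(nodes$modality)) {
        as.character(nodes$modality)
      } else {
        "other"
      }
    )
  }
  if (is.null(links) || length(links) == 0) {
    return(signed_network(NULL, nodes))
  }
  edges <- tibble::tibble(
    from = as.character(links$source),
    to = as.character(links$target),
    relation = if (!is.null(links$relation)) {
      as.character(links$relation)
    } else {
      NA_character_
    }
  )
  if (!is.null(links$polarity)) {
    edges$polarity <- as.numeric(links$polarity)
    if (anyNA(edges$polarity)) {
      miss <- is.na(edges$polarity)
      edges$polarity[miss] <- apply_vocabulary(edges$relation[miss], vocab)
    }
  } else {
    edges$polarity <- apply_vocabulary(edges$relation, vocab)
  }
  if (anyNA(edges$relation)) {
    edges$relation[is.na(edges$relation)] <-
      ifelse(edges$polarity[is.na(edges$relation)] > 0,
        "activation", "inhibition"
      )
  }
  signed_network(edges, nodes)
}

write_nodelink <- function(net, path) {
  obj <- list(
    directed = TRUE,
    multigraph = TRUE,
    nodes = net$nodes,
    links = tibble::tibble(
      source = net$edges$from,
      target = net$edges$to,
      relation = net$edges$relation,
      polarity = net$edges$polarity
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

read_graphml <- function(path, vocab) {
  g <- igraph::read_graph(path, format = "graphml")
  vat <- igraph::vertex_attr(g)
  ids <- if (!is.null(vat$name)) {
    as.character(vat$name)
  } else if (!is.null(vat$id)) {
    as.character(vat$id)
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  nodes <- tibble::tibble(
    id = ids,
    modality = if (!is.null(vat$modality)) {
      as.character(vat$modality)
    } else {
      "other"
    }
  )
  if (igraph::ecount(g) == 0) {
    return(signed_network(NULL, nodes))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  eat <- igraph::edge_attr(g)
  edges <- tibble::tibble(
    from = ids[el[, 1]],
    to = ids[el[, 2]],
    relation = if (!is.null(eat$relation)) {
      as.character(eat$relation)
    } else {
      NA_character_
    }
  )
  if (!is.null(eat$polarity)) {
    edges$polarity <- as.numeric(eat$polarity)
  } else {
    edges$polarity <- apply_vocabulary(edges$relation, vocab)
  }
  if (anyNA(edges$relation)) {
    edges$relation[is.na(edges$relation)] <-
      ifelse(edges$polarity[is.na(edges$relation)] > 0,
        "activation", "inhibition"
      )
  }
  signed_network(edges, nodes)
}

write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = net$edges$from, to = net$edges$to,
      relation = net$edges$relation, polarity = net$edges$polarity,
      stringsAsFactors = FALSE
    ),
    directed = TRUE,
    vertices = data.frame(
      name = net$nodes$id, modality = net$nodes$modality,
      stringsAsFactors = FALSE
    )
  )
  igraph::write_graph(g, path, format = "graphml")
}
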