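#' Specification for a synthetic multimodal network
#'
#' Describes a layered random network emulating the structure of curated
#' drug-protein-disease knowledge graphs: drug -> protein binding edges,
#' protein -> protein signalling edges (both signed, inhibitory with
#' probability `rho`), and protein -> indication / protein -> phenotype
#' association edges (unsigned in source databases, inferred as activation,
#' hence always `+1` here). *Planted mechanisms* are sign-consistent
#' amplifier gadgets connecting a chosen drug to a chosen target with
#' `width^(k-1)` paths of every exact length `k = 2..depth`, all of the
#' desired direction, so that each planted pair passes the default
#' prioritization criteria by construction (relative effect 1 at every
#' lmax, strictly growing totals). Planted drugs and gadget proteins carry
#' no background out-edges, so background noise never dilutes a planted
#' pair's effect.
#'
#' @param n_drugs,n_proteins,n_indications,n_phenotypes Layer sizes.
#' @param density Named edge densities per layer pair
#'   (`drug_protein`, `protein_protein`, `protein_indication`,
#'   `protein_phenotype`), each the Bernoulli probability of an ordered
#'   pair being connected.
#' @param rho Inhibition fraction in `[0, 1]` for the signed
#'   (drug -> protein and protein -> protein) edges.
#' @param planted A data frame with columns `drug`, `target`, `direction`
#'   (`"inhibition"`/`"activation"`), `depth` (maximum mechanism path
#'   length), `width` (paths multiply as `width^(k-1)`), or `NULL`/number:
#'   a number `n` plants `n` inhibitory drug -> indication mechanisms with
#'   `depth = 8`, `width = 2` on the first `n` drugs and indications.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_drugs = 10, n_proteins = 100,
                           n_indications = 5, n_phenotypes = 10,
                           density = c(
                             drug_protein = 0.03, protein_protein = 0.03,
                             protein_indication = 0.05,
                             protein_phenotype = 0.03
                           ),
                           rho = 0.3, planted = 3, seed = 7) {
  stopifnot(all(density >= 0), all(density <= 1), rho >= 0, rho <= 1)
  if (is.numeric(planted) && length(planted) == 1) {
    n_pl <- planted
    if (n_pl > n_drugs || n_pl > n_indications) {
      stop("cannot plant more mechanisms than drugs or indications",
        call. = FALSE
      )
    }
    planted <- if (n_pl == 0) {
      NULL
    } else {
      tibble::tibble(
        drug = paste0("D", seq_len(n_pl)),
        target = paste0("Ind", seq_len(n_pl)),
        direction = "inhibition", depth = 8L, width = 2L
      )
    }
  } else if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    stopifnot(all(
      c("drug", "target", "direction", "depth", "width") %in% names(planted)
    ))
  }
  structure(
    list(
      n_drugs = n_drugs, n_proteins = n_proteins,
      n_indications = n_indications, n_phenotypes = n_phenotypes,
      density = density, rho = rho, planted = planted, seed = seed
    ),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic multimodal signed network
#'
#' Realizes a [synthetic_spec()]: layered Bernoulli background edges plus
#' planted mechanism gadgets. Gadget intermediates are reserved from the
#' protein pool (an error if the pool is too small). The ground-truth
#' planted table is attached as the `"planted"` attribute.
#'
#' @param spec A [synthetic_spec()].
#' @return A [signed_network()] with modality annotations and a `"planted"`
#'   attribute.
#' @examples
#' net <- generate_network(synthetic_spec(n_drugs = 5, n_proteins = 30,
#'   planted = 1, seed = 1))
#' network_summary(net)$modalities
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drugs <- paste0("D", seq_len(spec$n_drugs))
  proteins <- paste0("P", seq_len(spec$n_proteins))
  indications <- paste0("Ind", seq_len(spec$n_indications))
  phenotypes <- paste0("Phe", seq_len(spec$n_phenotypes))
  nodes <- tibble::tibble(
    id = c(drugs, proteins, indications, phenotypes),
    modality = c(
      rep("drug", length(drugs)), rep("protein", length(proteins)),
      rep("indication", length(indications)),
      rep("phenotype", length(phenotypes))
    )
  )
  planted <- spec$planted
  gadget_edges <- NULL
  reserved <- character() # gadget proteins: no background out-edges
  shielded_drugs <- character()
  if (!is.null(planted) && nrow(planted) > 0) {
    bad <- setdiff(c(planted$drug, planted$target), nodes$id)
    if (length(bad) > 0) {
      stop("planted ids not in the network: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    need <- sum((planted$depth - 1) * planted$width)
    if (need > spec$n_proteins) {
      stop(
        "infeasible spec: planted mechanisms need ", need,
        " proteins but only ", spec$n_proteins, " are available",
        call. = FALSE
      )
    }
    pool <- proteins
    parts <- list()
    for (r in seq_len(nrow(planted))) {
      depth <- planted$depth[r]
      width <- planted$width[r]
      stopifnot(depth >= 2, width >= 1)
      layers <- vector("list", depth - 1)
      for (l in seq_len(depth - 1)) {
        layers[[l]] <- pool[seq_len(width)]
        pool <- pool[-seq_len(width)]
      }
      first_sign <- if (planted$direction[r] == "inhibition") -1 else 1
      first_rel <- if (first_sign < 0) "inhibition" else "activation"
      e <- list(tibble::tibble(
        from = planted$drug[r], to = layers[[1]],
        polarity = first_sign, relation = first_rel
      ))
      for (l in seq_len(depth - 2)) {
        e[[length(e) + 1]] <- tidyr::expand_grid(
          from = layers[[l]], to = layers[[l + 1]]
        ) |> dplyr::mutate(polarity = 1, relation = "activation")
      }
      for (l in seq_len(depth - 1)) {
        e[[length(e) + 1]] <- tibble::tibble(
          from = layers[[l]], to = planted$target[r],
          polarity = 1, relation = "association"
        )
      }
      parts[[r]] <- dplyr::bind_rows(e)
      reserved <- c(reserved, unlist(layers))
    }
    gadget_edges <- dplyr::bind_rows(parts)
    shielded_drugs <- unique(planted$drug)
  }

  bg_sources_d <- setdiff(drugs, shielded_drugs)
  bg_sources_p <- setdiff(proteins, reserved)
  layer_edges <- function(sources, targets, p, signed, rho, relation) {
    if (length(sources) == 0 || length(targets) == 0 || p == 0) {
      return(NULL)
    }
    grid <- tidyr::expand_grid(from = sources, to = targets)
    grid <- grid[grid$from != grid$to, ]
    keep <- stats::runif(nrow(grid)) < p
    grid <- grid[keep, ]
    if (nrow(grid) == 0) {
      return(NULL)
    }
    if (signed) {
      inh <- stats::runif(nrow(grid)) < rho
      grid$polarity <- ifelse(inh, -1, 1)
      grid$relation <- ifelse(inh, "inhibition", "activation")
    } else {
      grid$polarity <- 1
      grid$relation <- relation
    }
    grid
  }
  bg <- withr::with_seed(spec$seed, {
    dplyr::bind_rows(
      layer_edges(bg_sources_d, proteins, spec$density[["drug_protein"]],
        TRUE, spec$rho, NULL
      ),
      layer_edges(bg_sources_p, proteins, spec$density[["protein_protein"]],
        TRUE, spec$rho, NULL
      ),
      layer_edges(bg_sources_p, indications,
        spec$density[["protein_indication"]], FALSE, 0, "association"
      ),
      layer_edges(bg_sources_p, phenotypes,
        spec$density[["protein_phenotype"]], FALSE, 0, "association"
      )
    )
  })
  edges <- dplyr::bind_rows(gadget_edges, bg)
  net <- signed_network(edges, nodes)
  attr(net, "planted") <- planted
  net
}

#' Build a fixture network realizing a requested per-length path profile
#'
#' Constructs an acyclic graph on which the counting engine reproduces a
#' requested sequence of path counts exactly: for each requested length
#' `k`, `count` vertex-disjoint simple paths of exactly `k` edges from
#' `source` to `target`, of which `inhibitory` have effect `-1` (one
#' inhibitory first edge) and the rest `+1`. Counts are realized as layered
#' complete-bipartite gadgets whose widths multiply to the requested count,
#' so even large counts need few nodes. Because the graph is acyclic and
#' the gadgets share no intermediate vertices, the `"all"` and `"simple"`
#' variants agree and the per-exact-length breakdown of [lmax_sweep()]
#' matches the request exactly.
#'
#' @param profile A data frame with columns `length` (`>= 1`), `count`
#'   (`>= 0`) and either `inhibitory` (integer count) or `fraction`
#'   (inhibitory fraction; `fraction * count` must be an integer —
#'   e.g. requesting 1 path, 80% inhibitory is infeasible and an error).
#' @param source,target Node ids to use for the endpoints.
#' @return A [signed_network()] realizing the profile for
#'   `(source, target)`.
#' @examples
#' net <- fixture_for_profile(
#'   data.frame(length = 2, count = 5, fraction = 0.8)
#' )
#' count_paths(net, "s", "t", lmax = 2)
#' @export
fixture_for_profile <- function(profile, source = "s", target = "t") {
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("length", "count") %in% names(profile)))
  if (!"inhibitory" %in% names(profile)) {
    stopifnot("fraction" %in% names(profile))
    inh <- profile$fraction * profile$count
    if (any(abs(inh - round(inh)) > 1e-9)) {
      bad <- which(abs(inh - round(inh)) > 1e-9)[1]
      stop(
        "infeasible profile: ", profile$fraction[bad], " * ",
        profile$count[bad], " inhibitory paths is not an integer",
        call. = FALSE
      )
    }
    profile$inhibitory <- round(inh)
  }
  if (any(profile$count < 0) || any(profile$inhibitory < 0) ||
    any(profile$inhibitory > profile$count) || any(profile$length < 1)) {
    stop("infeasible profile: counts must satisfy 0 <= inhibitory <= count",
      call. = FALSE
    )
  }
  if (anyDuplicated(profile$length)) {
    stop("duplicate `length` entries in profile", call. = FALSE)
  }
  node_counter <- 0L
  fresh <- function(n) { # intermediates namespaced by endpoint pair so two
    # fixtures over different sources can be merged into one network
    ids <- paste0(source, ".", target, ".v", node_counter + seq_len(n))
    node_counter <<- node_counter + n
    ids
  }
  # counts realized as products of layer widths; factor into small factors
  factor_widths <- function(count, n_layers) {
    if (n_layers == 0) {
      stopifnot(count == 1)
      return(integer())
    }
    widths <- integer()
    rem <- count
    for (f in rep(c(2:9), 50)) {
      if (length(widths) >= n_layers - 1 || rem == 1) break
      while (rem %% f == 0 && length(widths) < n_layers - 1) {
        widths <- c(widths, f)
        rem <- rem %/% f
      }
    }
    widths <- c(widths, rem) # any leftover (large prime) as one wide layer
    c(widths, rep(1L, n_layers - length(widths)))
  }
  gadget <- function(k, count, sign) {
    # `count` paths of exactly k edges, effect `sign`, private intermediates
    if (count == 0) {
      return(NULL)
    }
    if (k == 1) {
      # a direct edge; only one can exist per sign (edges are deduplicated)
      stopifnot(count == 1)
      return(tibble::tibble(
        from = source, to = target, polarity = sign,
        relation = if (sign > 0) "activation" else "inhibition"
      ))
    }
    widths <- factor_widths(count, k - 1)
    layers <- lapply(widths, fresh)
    e <- list(tibble::tibble(
      from = source, to = layers[[1]], polarity = sign,
      relation = if (sign > 0) "activation" else "inhibition"
    ))
    if (k > 2) {
      for (l in seq_len(k - 2)) {
        e[[length(e) + 1]] <- tidyr::expand_grid(
          from = layers[[l]], to = layers[[l + 1]]
        ) |> dplyr::mutate(polarity = 1, relation = "activation")
      }
    }
    e[[length(e) + 1]] <- tibble::tibble(
      from = layers[[k - 1]], to = target, polarity = 1,
      relation = "association"
    )
    dplyr::bind_rows(e)
  }
  parts <- list()
  for (r in seq_len(nrow(profile))) {
    k <- profile$length[r]
    parts[[length(parts) + 1]] <- gadget(k, profile$inhibitory[r], -1)
    parts[[length(parts) + 1]] <- gadget(
      k, profile$count[r] - profile$inhibitory[r], 1
    )
  }
  edges <- dplyr::bind_rows(parts)
  if (is.null(edges) || nrow(edges) == 0) {
    return(signed_network(NULL, tibble::tibble(
      id = c(source, target), modality = "other"
    )))
  }
  nodes <- tibble::tibble(
    id = unique(c(source, target, edges$from, edges$to))
  )
  nodes$modality <- "other"
  nodes$modality[nodes$id == source] <- "drug"
  nodes$modality[nodes$id == target] <- "indication"
  nodes$modality[!nodes$id %in% c(source, target)] <- "protein"
  signed_network(edges, nodes)
}
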