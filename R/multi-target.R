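#' Effect profile of one drug against several targets
#'
#' Scores a single drug against a set of target nodes of interest (an
#' indication and/or associated phenotypes), one independent path-counting
#' query per target. Targets unreachable from the drug get the distinct
#' no-path state (`NA` scores), never a zero.
#'
#' @param net A [signed_network()].
#' @param drug Drug node id.
#' @param targets Character vector of target node ids (indication and/or
#'   phenotypes), non-empty.
#' @param lmax Maximum path length, `>= 2` (at least one intermediate node).
#' @param variant `"all"` or `"simple"` (see [count_paths()]).
#' @param direction Direction for the `delta` column.
#' @return A tibble with one row per target: counts plus [effect_score()]
#'   columns.
#' @export
multi_target_profile <- function(net, drug, targets, lmax = 8,
                                 variant = c("all", "simple"),
                                 direction = c("inhibition", "activation")) {
  variant <- match.arg(variant)
  direction <- match.arg(direction)
  stopifnot(length(targets) >= 1)
  if (lmax < 2) stop("`lmax` must be >= 2 for drug-target queries",
      call. = FALSE
    )
  purrr::map(targets, function(t) {
    count_paths(net, drug, t, lmax = lmax, variant = variant)
  }) |>
    dplyr::bind_rows() |>
    effect_score(direction = direction)
}

#' Score every drug against a shared target set and rank
#'
#' Builds the drug-by-target matrix of normalized scores (the multi-target
#' heatmap) and ranks drugs by how many targets they affect in the desired
#' direction; ties are broken by the mean absolute normalized score over
#' the met targets, then by drug id. A no-path entry never counts as met.
#'
#' @param net A [signed_network()].
#' @param drugs Character vector of drug node ids.
#' @param targets Character vector of target node ids.
#' @param lmax,variant As in [multi_target_profile()].
#' @param direction Desired direction per target: either a single string
#'   (recycled) or a character vector parallel to `targets`, entries
#'   `"inhibition"` or `"activation"`.
#' @return An object of class `multi_target_ranking`: list with `scores`
#'   (long tibble drug x target) and `ranking` (one row per drug:
#'   `n_met`, `mean_abs_score`, `rank`).
#' @export
rank_multi_target <- function(net, drugs, targets, lmax = 8,
                              variant = c("all", "simple"),
                              direction = "inhibition") {
  variant <- match.arg(variant)
  direction <- rep_len(match.arg(direction,
    c("inhibition", "activation"),
    several.ok = TRUE
  ), length(targets))
  scores <- purrr::map(drugs, function(d) {
    multi_target_profile(net, d, targets, lmax = lmax, variant = variant) |>
      dplyr::mutate(desired = direction[match(.data$to, targets)])
  }) |>
    dplyr::bind_rows() |>
    dplyr::rename(drug = "from", target = "to")
  met <- function(score, desired, no_path) {
    !no_path & !is.na(score) &
      ifelse(desired == "inhibition", score < 0, score > 0)
  }
  scores$met <- met(scores$normalized_score, scores$desired, scores$no_path)
  ranking <- scores |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      n_met = sum(.data$met),
      mean_abs_score = ifelse(sum(.data$met) > 0,
        mean(abs(.data$normalized_score[.data$met])), 0
      ),
      .groups = "drop"
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$n_met), dplyr::desc(.data$mean_abs_score),
      .data$drug
    ) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(scores = scores, ranking = ranking),
    class = "multi_target_ranking"
  )
}

#' @export
print.multi_target_ranking <- function(x, ...) {
  cat("<multi_target_ranking> ", dplyr::n_distinct(x$scores$drug),
    " drugs x ", dplyr::n_distinct(x$scores$target), " targets\n",
    sep = ""
  )
  print(utils::head(x$ranking))
  invisible(x)
}

#' @describeIn rank_multi_target heatmap of normalized scores (drugs by
#'   targets; no-path cells blank).
#' @param object A `multi_target_ranking`.
#' @param ... Unused.
#' @export
autoplot.multi_target_ranking <- function(object, ...) {
  ggplot2::ggplot(
    object$scores,
    ggplot2::aes(.data$target, .data$drug, fill = .data$normalized_score)
  ) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "grey85", high = "#b2182b",
      midpoint = 0, limits = c(-1, 1), na.value = "white",
      name = "normalized\nscore"
    ) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = "Relative effect of drugs on targets",
      subtitle = "blue: inhibition, red: activation, white: no paths"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Aggregate effect of a drug combination on a target
#'
#' The effect of a set of drugs on a target is the aggregate over its
#' members: activatory and inhibitory counts are summed across the
#' per-drug queries (equivalently, the counts from a virtual super-source
#' connected by `+1` edges to every member drug, queried at `lmax + 1`).
#' A singleton combination is exactly the single-drug result. Paths are not
#' deduplicated across member drugs — they originate from distinct sources
#' even when they share intermediate nodes.
#'
#' @param net A [signed_network()].
#' @param drugs Character vector of distinct member drug ids (size >= 1).
#' @param target Target node id.
#' @param lmax Maximum per-drug path length, `>= 2`.
#' @param variant `"all"` or `"simple"`.
#' @param method `"sum"` (default) aggregates per-drug counts;
#'   `"supersource"` materializes the virtual super-source construction
#'   (identical result, used as an internal cross-check).
#' @param direction Direction for the `delta` column.
#' @return A one-row tibble: `drugs` (collapsed id string), `target`,
#'   counts and [effect_score()] columns.
#' @export
combination_effect <- function(net, drugs, target, lmax = 4,
                               variant = c("all", "simple"),
                               method = c("sum", "supersource"),
                               direction = c("inhibition", "activation")) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  direction <- match.arg(direction)
  stopifnot(length(drugs) >= 1, !anyDuplicated(drugs))
  if (lmax < 2) stop("`lmax` must be >= 2", call. = FALSE)
  missing <- setdiff(drugs, net$nodes$id)
  if (length(missing) > 0) {
    stop("drug(s) not in network: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (method == "sum") {
    per <- purrr::map(drugs, function(d) {
      count_paths(net, d, target, lmax = lmax, variant = variant)
    }) |>
      dplyr::bind_rows()
    act <- sum(per$activatory)
    inh <- sum(per$inhibitory)
  } else {
    ss <- "..supersource.."
    stopifnot(!ss %in% net$nodes$id)
    aug <- signed_network(
      dplyr::bind_rows(
        net$edges,
        tibble::tibble(
          from = ss, to = drugs, polarity = 1, relation = "activation"
        )
      ),
      dplyr::bind_rows(
        net$nodes,
        tibble::tibble(id = ss, modality = "other")
      )
    )
    cp <- count_paths(aug, ss, target, lmax = lmax + 1L, variant = variant)
    act <- cp$activatory
    inh <- cp$inhibitory
  }
  tibble::tibble(
    drugs = paste(drugs, collapse = "+"), target = target,
    lmax = as.integer(lmax), variant = variant,
    activatory = act, inhibitory = inh
  ) |>
    effect_score(direction = direction)
}

#' Enumerate and filter drug combinations against targets
#'
#' Evaluates every size-`k` combination from a drug pool against each
#' target, reusing per-drug counts (each (drug, target) query is computed
#' once). Combinations are filtered on the aggregate relative effect; with
#' `require_each = TRUE` every member drug must additionally pass the
#' threshold individually.
#'
#' @param net A [signed_network()].
#' @param pool Character vector of candidate drug ids.
#' @param k Combination size, `2 <= k <= length(pool)` (1 allowed, giving
#'   single drugs).
#' @param targets Character vector of target node ids.
#' @param lmax,variant,direction As in [combination_effect()].
#' @param threshold Minimum aggregate `delta` in the desired direction;
#'   `NULL` disables filtering (all combinations returned with scores).
#' @param require_each Also require each member drug's own `delta` to meet
#'   the threshold.
#' @return A tibble with one row per (combination, target) that passes the
#'   filter: member drug columns `drug_1..drug_k`, `target`, counts and
#'   score columns. The attribute `"n_evaluated"` records the number of
#'   combinations evaluated (`choose(length(pool), k)` per target).
#' @export
enumerate_combinations <- function(net, pool, k, targets, lmax = 4,
                                   variant = c("all", "simple"),
                                   direction = c(
                                     "inhibition", "activation"
                                   ),
                                   threshold = 0.75,
                                   require_each = FALSE) {
  variant <- match.arg(variant)
  direction <- match.arg(direction)
  pool <- sort(unique(pool)) # order-independence of results
  if (k > length(pool)) stop("`k` exceeds the pool size", call. = FALSE)
  stopifnot(k >= 1)
  combos <- utils::combn(pool, k, simplify = FALSE)
  per_drug <- tidyr::expand_grid(drug = pool, target = targets) |>
    dplyr::mutate(purrr::map2(.data$drug, .data$target, function(d, t) {
      cp <- count_paths(net, d, t, lmax = lmax, variant = variant)
      tibble::tibble(activatory = cp$activatory, inhibitory = cp$inhibitory)
    }) |> dplyr::bind_rows())
  rows <- list()
  for (combo in combos) {
    for (t in targets) {
      sub <- per_drug[per_drug$drug %in% combo & per_drug$target == t, ]
      act <- sum(sub$activatory)
      inh <- sum(sub$inhibitory)
      total <- act + inh
      eps <- if (direction == "inhibition") inh else act
      delta <- if (total > 0) eps / total else NA_real_
      pass <- is.null(threshold) ||
        (!is.na(delta) && delta >= threshold)
      if (pass && require_each && !is.null(threshold)) {
        each_eps <- if (direction == "inhibition") {
          sub$inhibitory
        } else {
          sub$activatory
        }
        each_tot <- sub$activatory + sub$inhibitory
        pass <- all(each_tot > 0 & each_eps / each_tot >= threshold)
      }
      if (pass) {
        row <- stats::setNames(
          as.list(combo), paste0("drug_", seq_len(k))
        )
        row$target <- t
        row$activatory <- act
        row$inhibitory <- inh
        row$total <- total
        row$delta <- delta
        row$normalized_score <- if (total > 0) (act - inh) / total else NA_real_
        rows[[length(rows) + 1]] <- tibble::as_tibble(row)
      }
    }
  }
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    cols <- c(
      stats::setNames(
        rep(list(character()), k), paste0("drug_", seq_len(k))
      ),
      list(
        target = character(), activatory = numeric(),
        inhibitory = numeric(), total = numeric(), delta = numeric(),
        normalized_score = numeric()
      )
    )
    tibble::as_tibble(cols)
  }
  attr(out, "n_evaluated") <- length(combos) * length(targets)
  out
}
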