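#' Prioritization criteria for drug-disease pairs
#'
#' A pair is prioritized when its relative effect is strong, stable across a
#' range of maximum path lengths, and supported by a growing body of paths:
#'
#' 1. **High effect with consistency**: `delta(direction) >= threshold` at
#'    at least `quota` of the lmax values in the range. An lmax with no
#'    paths at all counts as a failure at that lmax (no paths means no
#'    evidence of inhibition). The default quota is *all* values ("7/7"
#'    over the default `2:8` range); `quota = 6` gives the relaxed "6/7"
#'    rule.
#' 2. **Nonzero support**: paths must exist at every lmax counted toward
#'    the quota.
#' 3. **Increasing number of paths**: the total number of paths must
#'    strictly increase at every consecutive lmax step, i.e., novel paths
#'    appear at every step (can be disabled with
#'    `require_increasing = FALSE`).
#'
#' @param direction `"inhibition"` or `"activation"`.
#' @param threshold Relative-effect threshold in `(0, 1]`, default `0.75`.
#' @param lmax_range Ascending integer range, default `2:8`.
#' @param quota How many lmax values must meet the threshold; default all.
#' @param require_increasing Require strictly increasing totals.
#' @return An object of class `prioritization_criteria`.
#' @export
prioritization_criteria <- function(direction = c("inhibition", "activation"),
                                    threshold = 0.75, lmax_range = 2:8,
                                    quota = length(lmax_range),
                                    require_increasing = TRUE) {
  direction <- match.arg(direction)
  lmax_range <- as.integer(lmax_range)
  stopifnot(
    threshold > 0, threshold <= 1,
    length(lmax_range) >= 1, !is.unsorted(lmax_range, strictly = TRUE),
    quota >= 1, quota <= length(lmax_range)
  )
  structure(
    list(
      direction = direction, threshold = threshold,
      lmax_range = lmax_range, quota = as.integer(quota),
      require_increasing = isTRUE(require_increasing)
    ),
    class = "prioritization_criteria"
  )
}

#' @export
print.prioritization_criteria <- function(x, ...) {
  cat("<prioritization_criteria> ", x$direction, " >= ", x$threshold,
    " at ", x$quota, "/", length(x$lmax_range), " lmax in [",
    min(x$lmax_range), ", ", max(x$lmax_range), "]",
    if (x$require_increasing) ", strictly increasing totals", "\n",
    sep = ""
  )
  invisible(x)
}

#' Prioritize drug-disease pairs from per-lmax profiles
#'
#' Applies the [prioritization_criteria()] to a table of per-pair, per-lmax
#' path counts and returns an audited, ranked candidate list.
#'
#' @param profiles A data frame with one row per (pair, lmax): columns
#'   `source`, `target`, `lmax`, `total`, and either
#'   `activatory`/`inhibitory` counts or a precomputed `delta` column
#'   (fraction of paths in the criteria's direction). Every pair must cover
#'   the criteria's full lmax range.
#' @param criteria A [prioritization_criteria()].
#' @return An object of class `prioritization`: a list with `pairs` (one
#'   row per pair: `source`, `target`, `prioritized`, per-criterion flags
#'   `crit_effect`, `crit_support`, `crit_increasing`, `first_failure`,
#'   `mean_delta`, `total_at_max`, `rank`) and the `criteria` used.
#'   Prioritized pairs are ranked by mean delta (descending), ties broken
#'   by total paths at the largest lmax (descending), then by pair id.
#' @examples
#' prof <- data.frame(
#'   source = "d", target = "x", lmax = 2:8,
#'   total = c(1, 4, 20, 50, 100, 400, 1000),
#'   delta = c(.8, .9, 1, 1, .8, .9, .8)
#' )
#' prioritize_pairs(prof, prioritization_criteria())
#' @export
prioritize_pairs <- function(profiles, criteria = prioritization_criteria()) {
  stopifnot(inherits(criteria, "prioritization_criteria"))
  profiles <- tibble::as_tibble(profiles)
  if (!"total" %in% names(profiles) &&
    all(c("activatory", "inhibitory") %in% names(profiles))) {
    profiles$total <- profiles$activatory + profiles$inhibitory
  }
  stopifnot(all(c("source", "target", "lmax", "total") %in% names(profiles)))
  if (!"delta" %in% names(profiles)) {
    stopifnot(all(c("activatory", "inhibitory") %in% names(profiles)))
    eps <- if (criteria$direction == "inhibition") {
      profiles$inhibitory
    } else {
      profiles$activatory
    }
    profiles$delta <- ifelse(profiles$total > 0, eps / profiles$total,
      NA_real_
    )
  }
  rng <- criteria$lmax_range
  audit_one <- function(df) {
    df <- df[order(df$lmax), ]
    if (!identical(as.integer(df$lmax), rng)) {
      stop("profile for pair (", df$source[1], ", ", df$target[1],
        ") does not cover the criteria's lmax range",
        call. = FALSE
      )
    }
    ok_effect <- df$total > 0 & !is.na(df$delta) &
      df$delta >= criteria$threshold
    crit_effect <- sum(ok_effect) >= criteria$quota
    crit_support <- sum(df$total > 0) >= criteria$quota
    incr_ok <- diff(df$total) > 0
    crit_increasing <- !criteria$require_increasing || all(incr_ok)
    first_failure <- NA_character_
    if (!crit_effect) {
      at <- df$lmax[!ok_effect][1]
      first_failure <- paste0("effect@lmax", at)
    } else if (!crit_support) {
      at <- df$lmax[df$total == 0][1]
      first_failure <- paste0("support@lmax", at)
    } else if (!crit_increasing) {
      at <- which(!incr_ok)[1]
      first_failure <- paste0(
        "increasing@lmax", df$lmax[at], "-", df$lmax[at + 1]
      )
    }
    tibble::tibble(
      crit_effect = crit_effect,
      crit_support = crit_support,
      crit_increasing = crit_increasing,
      prioritized = crit_effect && crit_support && crit_increasing,
      first_failure = first_failure,
      mean_delta = mean(ifelse(df$total > 0, df$delta, 0)),
      total_at_max = df$total[nrow(df)]
    )
  }
  pairs <- profiles |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::group_modify(~ audit_one(.x |>
      dplyr::mutate(source = .y$source, target = .y$target))) |>
    dplyr::ungroup()
  pairs <- pairs |>
    dplyr::arrange(
      dplyr::desc(.data$prioritized), dplyr::desc(.data$mean_delta),
      dplyr::desc(.data$total_at_max), .data$source, .data$target
    ) |>
    dplyr::mutate(rank = ifelse(.data$prioritized,
      cumsum(.data$prioritized), NA_integer_
    ))
  structure(list(pairs = pairs, criteria = criteria), class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  cat("<prioritization> ", sum(x$pairs$prioritized), " of ",
    nrow(x$pairs), " pairs prioritized\n",
    sep = ""
  )
  print(x$criteria)
  invisible(x)
}

#' @describeIn prioritize_pairs broom-style per-pair audit table.
#' @param x A `prioritization` object.
#' @param ... Unused.
#' @export
tidy.prioritization <- function(x, ...) {
  x$pairs
}

#' @describeIn prioritize_pairs broom-style one-row summary.
#' @export
glance.prioritization <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_prioritized = sum(x$pairs$prioritized),
    direction = x$criteria$direction,
    threshold = x$criteria$threshold,
    quota = x$criteria$quota,
    lmax_min = min(x$criteria$lmax_range),
    lmax_max = max(x$criteria$lmax_range),
    require_increasing = x$criteria$require_increasing
  )
}

#' Recovery of reference positives in a prioritized list
#'
#' The validation metric of the method: the fraction of prioritized pairs
#' that appear in a reference list of positive drug-disease pairs (e.g.,
#' clinically investigated combinations).
#'
#' @param prioritized Data frame with columns `source` and `target`
#'   (typically `tidy()` of a [prioritize_pairs()] result filtered to
#'   `prioritized`), or a `prioritization` object (filtered internally).
#' @param positives Data frame with columns `source` and `target`.
#' @return A one-row tibble: `hits`, `size`, `ratio` (NA when `size` is 0),
#'   and `display` following the "hits/size (xx.xx%)" convention with the
#'   percentage truncated (not rounded) to two decimals; an empty list is
#'   displayed as "0/0".
#' @examples
#' recovery_rate(
#'   data.frame(source = "d1", target = "x"),
#'   data.frame(source = c("d1", "d2"), target = c("x", "y"))
#' )
#' @export
recovery_rate <- function(prioritized, positives) {
  if (inherits(prioritized, "prioritization")) {
    prioritized <- dplyr::filter(prioritized$pairs, .data$prioritized)
  }
  prioritized <- tibble::as_tibble(prioritized)
  positives <- tibble::as_tibble(positives)
  key <- function(df) paste(df$source, df$target, sep = "\r")
  size <- nrow(prioritized)
  hits <- sum(key(prioritized) %in% key(positives))
  ratio <- if (size > 0) hits / size else NA_real_
  display <- if (size > 0) {
    paste0(hits, "/", size, " (", truncate_pct(100 * ratio), "%)")
  } else {
    "0/0"
  }
  tibble::tibble(hits = hits, size = size, ratio = ratio, display = display)
}

# truncate (not round) a percentage to two decimals, as conventionally
# printed ("3.19" from 3.1986)
truncate_pct <- function(x) {
  sprintf("%.2f", trunc(x * 100) / 100)
}

#' Chance level of picking a true positive pair at random
#'
#' @param n_positive_pairs Number of reference positive drug-disease pairs.
#' @param n_drugs,n_diseases Numbers of unique drugs and diseases screened.
#' @return A one-row tibble: `combinations` (`n_drugs * n_diseases`),
#'   `chance_pct` (raw percentage), and `chance_display` (truncated to two
#'   decimals).
#' @examples
#' chance_level(5151, 610, 264) # 161040 combinations, 3.19%
#' @export
chance_level <- function(n_positive_pairs, n_drugs, n_diseases) {
  stopifnot(n_positive_pairs > 0)
  if (n_drugs <= 0 || n_diseases <= 0) {
    stop("`n_drugs` and `n_diseases` must be positive", call. = FALSE)
  }
  combinations <- n_drugs * n_diseases
  pct <- 100 * n_positive_pairs / combinations
  tibble::tibble(
    combinations = combinations,
    chance_pct = pct,
    chance_display = truncate_pct(pct)
  )
}

#' Area under the ROC curve for per-pair scores
#'
#' Rank-based AUROC (ties contribute 0.5) of relative-effect scores against
#' a positive/negative labelling, computed with \pkg{pROC}.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical (or 0/1) vector of the same length.
#' @return The AUROC as a single number in `[0, 1]`.
#' @export
auroc_for_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )))
}

#' Shortest-path baseline for drug-disease candidate pairs
#'
#' The conventional network-proximity baseline: for every (drug, disease)
#' pair with a directed path, report the shortest path length and classify
#' all shortest paths by their sign product. A pair is a baseline candidate
#' when at least one shortest path has the desired direction; pairs whose
#' shortest paths disagree in sign are flagged `mixed`. Because any walk
#' whose length equals the shortest distance is necessarily a simple
#' shortest path, signed shortest-path counts are obtained from the exact-
#' length breakdown of the walk-counting engine.
#'
#' @param net A [signed_network()].
#' @param drugs,diseases Character vectors of node ids.
#' @param direction Desired effect, `"inhibition"` or `"activation"`.
#' @param max_length Ignore pairs whose shortest path exceeds this length.
#' @return A tibble with one row per connected pair: `source`, `target`,
#'   `length`, `activatory`, `inhibitory` (counts of shortest paths by
#'   sign), `candidate`, `mixed`. The attribute `"length_histogram"` holds
#'   the frequency table of shortest-path lengths.
#' @export
shortest_path_baseline <- function(net, drugs, diseases,
                                   direction = c("inhibition", "activation"),
                                   max_length = 8) {
  direction <- match.arg(direction)
  stopifnot(inherits(net, "signed_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")],
    directed = TRUE,
    vertices = data.frame(name = net$nodes$id)
  )
  d <- igraph::distances(g,
    v = drugs, to = diseases, mode = "out",
    algorithm = "unweighted"
  )
  rows <- list()
  for (s in drugs) {
    for (t in diseases) {
      len <- d[s, t]
      if (!is.finite(len) || len < 1 || len > max_length) next
      cp <- count_paths(net, s, t, lmax = as.integer(len), variant = "all")
      byl <- attr(cp, "by_length")
      act <- byl$activatory[len]
      inh <- byl$inhibitory[len]
      want <- if (direction == "inhibition") inh else act
      rows[[length(rows) + 1]] <- tibble::tibble(
        source = s, target = t, length = as.integer(len),
        activatory = act, inhibitory = inh,
        candidate = want > 0, mixed = act > 0 && inh > 0
      )
    }
  }
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(
      source = character(), target = character(), length = integer(),
      activatory = numeric(), inhibitory = numeric(),
      candidate = logical(), mixed = logical()
    )
  }
  attr(out, "length_histogram") <- table(out$length)
  out
}
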