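#' Relative effect and normalized score from path counts
#'
#' Given activatory/inhibitory path counts for a pair, the *relative effect*
#' for a direction of interest is the fraction of paths with that effect:
#' `delta = inhibitory / total` for inhibition (analogously for activation),
#' a value in `[0, 1]`. The *normalized score*
#' `(activatory - inhibitory) / total` rescales this to `[-1, +1]`, where
#' `-1` is full inhibition, `+1` full activation and `0` a cancelling
#' effect. A pair with no paths at all is a distinct state — reported as
#' `NA` (`no_path = TRUE`), never as `0`.
#'
#' @param counts A data frame with columns `activatory` and `inhibitory`
#'   (e.g., the output of [count_paths()]), any number of rows.
#' @param direction `"inhibition"` or `"activation"`: which effect `delta`
#'   should measure.
#' @return The input tibble with columns `delta`, `normalized_score`, and
#'   `no_path` appended. `delta(inhibition) + delta(activation) = 1`
#'   whenever paths exist.
#' @examples
#' effect_score(data.frame(activatory = 1, inhibitory = 4))
#' @export
effect_score <- function(counts, direction = c("inhibition", "activation")) {
  direction <- match.arg(direction)
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("activatory", "inhibitory") %in% names(counts)))
  total <- counts$activatory + counts$inhibitory
  eps <- if (direction == "inhibition") counts$inhibitory else counts$activatory
  delta <- ifelse(total > 0, eps / total, NA_real_)
  normalized <- ifelse(total > 0,
    (counts$activatory - counts$inhibitory) / total, NA_real_
  )
  counts$total <- total
  counts$delta <- delta
  counts$normalized_score <- normalized
  counts$no_path <- total == 0
  counts
}

#' Sweep path counts over a range of maximum path lengths
#'
#' Runs the counting engine for a single `(source, target)` pair across an
#' inclusive range of `lmax` values, the substrate of the prioritization
#' criteria. A single engine run at the largest `lmax` serves the whole
#' range: cumulative counts at smaller `lmax` are prefix sums of the
#' per-exact-length breakdown, so totals are non-decreasing in `lmax` by
#' construction.
#'
#' @param net A [signed_network()].
#' @param from,to Node ids.
#' @param lmax_range Inclusive integer range of maximum path lengths,
#'   ascending (default `2:8`).
#' @param variant `"all"` or `"simple"` (see [count_paths()]).
#' @param direction Direction for the `delta` column.
#' @return A tibble of class `lmax_sweep` with one row per `lmax`:
#'   cumulative `activatory`, `inhibitory`, `total`, plus the per-step
#'   breakdown `step_activatory`/`step_inhibitory` (paths of length exactly
#'   `lmax`), and the [effect_score()] columns.
#' @examples
#' net <- signed_network(data.frame(
#'   from = c("d", "p"), to = c("p", "x"), polarity = c(1, -1)
#' ))
#' lmax_sweep(net, "d", "x", 2:4)
#' @export
lmax_sweep <- function(net, from, to, lmax_range = 2:8,
                       variant = c("all", "simple"),
                       direction = c("inhibition", "activation")) {
  variant <- match.arg(variant)
  direction <- match.arg(direction)
  lmax_range <- as.integer(lmax_range)
  if (length(lmax_range) == 0 || is.unsorted(lmax_range, strictly = TRUE)) {
    stop("`lmax_range` must be a non-empty ascending integer range",
      call. = FALSE
    )
  }
  top <- max(lmax_range)
  cp <- count_paths(net, from, to, lmax = top, variant = variant)
  by_len <- attr(cp, "by_length")
  empty_bonus <- if (from == to) 1 else 0 # zero-length path for s == t
  cum_act <- cumsum(by_len$activatory) + empty_bonus
  cum_inh <- cumsum(by_len$inhibitory)
  out <- tibble::tibble(
    from = from, to = to, lmax = lmax_range, variant = variant,
    activatory = cum_act[lmax_range],
    inhibitory = cum_inh[lmax_range],
    step_activatory = by_len$activatory[lmax_range],
    step_inhibitory = by_len$inhibitory[lmax_range]
  )
  out <- effect_score(out, direction = direction)
  class(out) <- c("lmax_sweep", class(out))
  out
}

#' Heatmap-style plot of an lmax sweep
#'
#' @param object An [lmax_sweep()] result.
#' @param ... Unused.
#' @return A ggplot: total paths (log scale) and normalized score against
#'   `lmax`.
#' @export
autoplot.lmax_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df_long <- tidyr::pivot_longer(
    dplyr::transmute(df,
      lmax = .data$lmax,
      `total paths` = .data$total,
      `normalized score` = .data$normalized_score
    ),
    -"lmax",
    names_to = "panel", values_to = "value"
  )
  ggplot2::ggplot(df_long, ggplot2::aes(.data$lmax, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = "maximum path length (lmax)", y = NULL,
      title = paste0(df$from[1], " → ", df$to[1], " (", df$variant[1],
        " paths)"
      )
    ) +
    ggplot2::theme_minimal()
}
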