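# The worked three-pair example: per-lmax totals and inhibitory fractions
# over the range 2..8; pair A passes all criteria, pair B dips below the
# threshold at lmax 3, pair C gains no new paths between lmax 2 and 3.
worked_profiles <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      source = "dA", target = "x", lmax = 2:8,
      total = c(1, 4, 20, 50, 100, 400, 1000),
      delta = c(.80, .90, 1, 1, .80, .90, .80)
    ),
    tibble::tibble(
      source = "dB", target = "x", lmax = 2:8,
      total = c(1, 4, 20, 50, 100, 400, 1000),
      delta = c(.80, .70, 1, 1, .80, .90, .80)
    ),
    tibble::tibble(
      source = "dC", target = "x", lmax = 2:8,
      total = c(1, 1, 20, 50, 100, 400, 1000),
      delta = c(.80, .90, 1, 1, .80, .90, .80)
    )
  )
}

test_that("worked example: A prioritized, B fails effect, C fails growth", {
  res <- prioritize_pairs(worked_profiles(), prioritization_criteria())
  pairs <- tidy(res)
  a <- pairs[pairs$source == "dA", ]
  b <- pairs[pairs$source == "dB", ]
  c_ <- pairs[pairs$source == "dC", ]
  expect_true(a$prioritized)
  expect_true(is.na(a$first_failure))
  expect_false(b$prioritized)
  expect_equal(b$first_failure, "effect@lmax3")
  expect_false(c_$prioritized)
  expect_equal(c_$first_failure, "increasing@lmax2-3")
  g <- glance(res)
  expect_equal(g$n_prioritized, 1)
  expect_equal(g$n_pairs, 3)
})

test_that("relaxed 6/7 quota admits the pair that dips once", {
  res <- prioritize_pairs(
    worked_profiles(),
    prioritization_criteria(quota = 6)
  )
  pairs <- tidy(res)
  expect_true(pairs$prioritized[pairs$source == "dB"])
  expect_false(pairs$prioritized[pairs$source == "dC"]) # growth still fails
})

test_that("tightening threshold or quota never grows the prioritized list", {
  withr::with_seed(5, {
    profs <- purrr::map(1:25, function(i) {
      tibble::tibble(
        source = paste0("d", i), target = "x", lmax = 2:8,
        total = cumsum(sample(0:5, 7, replace = TRUE)),
        delta = round(runif(7), 2)
      )
    }) |> dplyr::bind_rows()
  })
  n_pri <- function(th, q) {
    sum(tidy(prioritize_pairs(
      profs, prioritization_criteria(threshold = th, quota = q)
    ))$prioritized)
  }
  for (th in c(0.25, 0.5, 0.75)) {
    expect_gte(n_pri(th, 5), n_pri(th + 0.1, 5))
    expect_gte(n_pri(th, 5), n_pri(th, 6))
  }
})

test_that("activation on a target-negated network mirrors inhibition", {
  net <- random_signed_network(10, p = 0.35, seed = 17)
  neg <- negate_into_target(net, "n10")
  prof <- function(n, dir) {
    lmax_sweep(n, "n1", "n10", 2:5, direction = dir) |>
      dplyr::transmute(
        source = "n1", target = "n10", lmax = .data$lmax,
        total = .data$total, delta = .data$delta
      )
  }
  crit_inh <- prioritization_criteria("inhibition",
    threshold = 0.5,
    lmax_range = 2:5, quota = 3
  )
  crit_act <- prioritization_criteria("activation",
    threshold = 0.5,
    lmax_range = 2:5, quota = 3
  )
  res_inh <- tidy(prioritize_pairs(prof(net, "inhibition"), crit_inh))
  res_act <- tidy(prioritize_pairs(prof(neg, "activation"), crit_act))
  expect_equal(res_inh$prioritized, res_act$prioritized)
  expect_equal(res_inh$mean_delta, res_act$mean_delta)
})

test_that("an lmax without paths fails the effect criterion there", {
  prof <- tibble::tibble(
    source = "d", target = "x", lmax = 2:4,
    total = c(0, 5, 10), delta = c(NA, 1, 1)
  )
  res <- tidy(prioritize_pairs(
    prof, prioritization_criteria(lmax_range = 2:4)
  ))
  expect_false(res$prioritized)
  expect_equal(res$first_failure, "effect@lmax2")
})

test_that("profile not covering the range is an error", {
  prof <- tibble::tibble(
    source = "d", target = "x", lmax = 2:5, total = 1:4, delta = 1
  )
  expect_error(
    prioritize_pairs(prof, prioritization_criteria(lmax_range = 2:8)),
    "lmax range"
  )
})

test_that("recovery rate counts intersections, handles the empty list", {
  r <- recovery_rate(
    data.frame(source = "d1", target = "x"),
    data.frame(source = c("d1", "d2"), target = c("x", "y"))
  )
  expect_equal(r$hits, 1)
  expect_equal(r$ratio, 1)
  expect_equal(r$display, "1/1 (100.00%)")
  r0 <- recovery_rate(
    data.frame(source = character(), target = character()),
    data.frame(source = "d1", target = "x")
  )
  expect_equal(r0$size, 0)
  expect_true(is.na(r0$ratio))
  expect_equal(r0$display, "0/0")
  # hits never exceed min(|prioritized|, |positives|)
  withr::with_seed(8, {
    for (i in 1:10) {
      p1 <- data.frame(
        source = sample(letters[1:5], 6, TRUE),
        target = sample(letters[1:5], 6, TRUE)
      ) |> unique()
      p2 <- data.frame(
        source = sample(letters[1:5], 6, TRUE),
        target = sample(letters[1:5], 6, TRUE)
      ) |> unique()
      r <- recovery_rate(p1, p2)
      expect_lte(r$hits, min(nrow(p1), nrow(p2)))
    }
  })
})

test_that("chance level reproduces the published screening arithmetic", {
  a <- chance_level(5151, 610, 264)
  expect_equal(a$combinations, 161040)
  expect_equal(a$chance_display, "3.19")
  expect_equal(a$chance_pct, 100 * 5151 / 161040)
  b <- chance_level(9537, 671, 378)
  expect_equal(b$combinations, 253638)
  expect_equal(b$chance_display, "3.76")
  expect_equal(chance_level(1, 1, 1)$chance_pct, 100)
  expect_error(chance_level(5, 0, 10), "positive")
})

test_that("AUROC follows rank conventions and is 0.5 under the null", {
  expect_equal(
    auroc_for_scores(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE)),
    1
  )
  expect_equal(
    auroc_for_scores(rep(1, 10), rep(c(TRUE, FALSE), 5)),
    0.5
  )
  expect_error(auroc_for_scores(1:3, c(TRUE, TRUE, TRUE)), "label")
  # labels independent of scores: AUROC concentrates at 0.5; with n = 2000
  # and 30% positives one replicate has sd ~ 0.014, so test the mean of 10
  # replicates (sd ~ 0.0045) and a generous per-replicate envelope
  aurocs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      scores <- runif(2000)
      labels <- runif(2000) < 0.3
    })
    auroc_for_scores(scores, labels)
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.02)
  expect_true(all(abs(aurocs - 0.5) < 0.07))
})

test_that("shortest-path baseline classifies direct chains and skips
           disconnected pairs", {
  net <- signed_network(data.frame(
    from = c("d", "p"), to = c("p", "x"), polarity = c(1, -1)
  ))
  res <- shortest_path_baseline(net, "d", "x")
  expect_equal(res$length, 2L)
  expect_true(res$candidate)
  expect_false(res$mixed)
  none <- shortest_path_baseline(
    signed_network(
      data.frame(from = "d", to = "p", polarity = 1),
      nodes = data.frame(id = c("d", "p", "x"))
    ),
    "d", "x"
  )
  expect_equal(nrow(none), 0)
})

test_that("baseline candidates have paths at lmax equal to their length", {
  for (seed in 1:5) {
    net <- random_signed_network(10, p = 0.3, seed = 500 + seed, dag = TRUE)
    res <- shortest_path_baseline(net, c("n1", "n2"), c("n9", "n10"))
    for (i in seq_len(nrow(res))) {
      cp <- count_paths(net, res$source[i], res$target[i], res$length[i])
      expect_gt(cp$total, 0)
      # shortest-path sign counts agree with the exact-length breakdown
      byl <- attr(cp, "by_length")
      expect_equal(res$activatory[i], byl$activatory[res$length[i]])
      expect_equal(res$inhibitory[i], byl$inhibitory[res$length[i]])
    }
  }
})
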