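test_that("hand-enumerable base cases count correctly", {
  # single inhibitory edge
  net <- signed_network(data.frame(from = "s", to = "t", polarity = -1))
  cp <- count_paths(net, "s", "t", lmax = 1)
  expect_equal(cp$activatory, 0)
  expect_equal(cp$inhibitory, 1)

  # two parallel routes of opposite effect
  net2 <- signed_network(data.frame(
    from = c("s", "a", "s", "b"), to = c("a", "t", "b", "t"),
    polarity = c(1, 1, 1, -1)
  ))
  cp2 <- count_paths(net2, "s", "t", lmax = 2)
  expect_equal(cp2$activatory, 1)
  expect_equal(cp2$inhibitory, 1)
  expect_equal(cp2$total, 2)
})

test_that("cycles are walked by the all variant and avoided by simple", {
  # s -> a -> t with the feedback edge a -> s, all activatory
  net <- signed_network(data.frame(
    from = c("s", "a", "a"), to = c("a", "t", "s"), polarity = 1
  ))
  all6 <- count_paths(net, "s", "t", lmax = 6, variant = "all")
  expect_equal(all6$activatory, 3) # lengths 2, 4, 6 through the loop
  expect_equal(all6$inhibitory, 0)
  simple6 <- count_paths(net, "s", "t", lmax = 6, variant = "simple")
  expect_equal(simple6$activatory, 1)
})

test_that("disconnected pairs give zero counts and the no-path state", {
  net <- signed_network(
    data.frame(from = "a", to = "b", polarity = 1),
    nodes = data.frame(id = c("a", "b", "s", "t"))
  )
  for (v in c("all", "simple")) {
    cp <- count_paths(net, "s", "t", lmax = 5, variant = v)
    expect_equal(cp$total, 0)
    sc <- effect_score(cp)
    expect_true(sc$no_path)
    expect_true(is.na(sc$delta))
    expect_true(is.na(sc$normalized_score))
  }
})

test_that("degenerate query s == t returns one activatory (empty) path", {
  net <- signed_network(data.frame(
    from = c("s", "a"), to = c("a", "s"), polarity = c(1, -1)
  ))
  for (v in c("all", "simple")) {
    cp <- count_paths(net, "s", "s", lmax = 4, variant = v)
    expect_equal(cp$activatory, 1, label = v)
    expect_equal(cp$inhibitory, 0, label = v)
  }
})

test_that("unknown ids and invalid lmax are errors", {
  net <- signed_network(data.frame(from = "a", to = "b", polarity = 1))
  expect_error(count_paths(net, "zzz", "b", 2), "unknown node")
  expect_error(count_paths(net, "a", "zzz", 2), "unknown node")
  expect_error(count_paths(net, "a", "b", 0), "lmax")
})

test_that("both variants match brute-force enumeration on random graphs", {
  for (seed in 1:40) {
    n <- 6 + (seed %% 7) # 6..12 nodes
    net <- random_signed_network(n, p = 0.3, p_inh = 0.5, seed = seed)
    lmax <- 3 + (seed %% 3) # 3..5
    s <- "n1"
    t <- paste0("n", n)
    expected_all <- oracle_count_walks(net, s, t, lmax)
    got_all <- count_paths(net, s, t, lmax, variant = "all")
    expect_equal(got_all$activatory, expected_all[["activatory"]],
      label = paste("walks act seed", seed)
    )
    expect_equal(got_all$inhibitory, expected_all[["inhibitory"]],
      label = paste("walks inh seed", seed)
    )
    expected_sp <- oracle_count_simple(net, s, t, lmax)
    got_sp <- count_paths(net, s, t, lmax, variant = "simple")
    expect_equal(got_sp$activatory, expected_sp[["activatory"]],
      label = paste("simple act seed", seed)
    )
    expect_equal(got_sp$inhibitory, expected_sp[["inhibitory"]],
      label = paste("simple inh seed", seed)
    )
    # conservation and containment
    expect_equal(got_all$total, got_all$activatory + got_all$inhibitory)
    expect_lte(got_sp$total, got_all$total)
  }
})

test_that("flipping the sign of every edge into the target swaps counts", {
  # every source->target path contains exactly one in-edge of the target,
  # so this negation flips every path effect exactly once
  for (seed in 1:10) {
    net <- random_signed_network(9, p = 0.3, seed = 100 + seed)
    neg <- negate_into_target(net, "n9")
    for (v in c("all", "simple")) {
      a <- count_paths(net, "n1", "n9", 5, variant = v)
      b <- count_paths(neg, "n1", "n9", 5, variant = v)
      expect_equal(a$activatory, b$inhibitory, label = paste(v, seed))
      expect_equal(a$inhibitory, b$activatory, label = paste(v, seed))
    }
  }
})

test_that("full negation swaps counts when all path lengths are odd", {
  # layered chains of fixed odd length: (-1)^length = -1 flips every path
  net <- fixture_for_profile(data.frame(length = 3, count = 12, inhibitory = 5))
  neg <- negate_network(net)
  a <- count_paths(net, "s", "t", 3)
  b <- count_paths(neg, "s", "t", 3)
  expect_equal(a$activatory, b$inhibitory)
  expect_equal(a$inhibitory, b$activatory)
})

test_that("simple and all variants coincide on acyclic graphs", {
  for (seed in 1:10) {
    net <- random_signed_network(10, p = 0.35, seed = 200 + seed, dag = TRUE)
    a <- count_paths(net, "n1", "n10", 6, variant = "all")
    s <- count_paths(net, "n1", "n10", 6, variant = "simple")
    expect_equal(a$activatory, s$activatory, label = seed)
    expect_equal(a$inhibitory, s$inhibitory, label = seed)
  }
})

test_that("totals are non-decreasing in lmax", {
  for (seed in 1:8) {
    net <- random_signed_network(10, p = 0.3, seed = 300 + seed)
    for (v in c("all", "simple")) {
      sw <- lmax_sweep(net, "n1", "n10", 1:6, variant = v)
      expect_true(all(diff(sw$total) >= 0), label = paste(v, seed))
      expect_equal(sw$total, sw$activatory + sw$inhibitory)
    }
  }
})

test_that("sweep cumulative counts equal per-lmax engine runs", {
  net <- random_signed_network(10, p = 0.3, seed = 77)
  sw <- lmax_sweep(net, "n1", "n10", 2:6, variant = "all")
  for (i in seq_len(nrow(sw))) {
    cp <- count_paths(net, "n1", "n10", sw$lmax[i], variant = "all")
    expect_equal(sw$activatory[i], cp$activatory)
    expect_equal(sw$inhibitory[i], cp$inhibitory)
  }
})

test_that("unreachable decorations never change counts", {
  net <- random_signed_network(8, p = 0.35, seed = 55)
  base <- count_paths(net, "n1", "n8", 5)
  # add a component unreachable from n1 and not reaching n8
  extra <- signed_network(
    dplyr::bind_rows(
      net$edges,
      data.frame(
        from = c("z1", "z2", "n8"), to = c("z2", "z1", "z1"),
        polarity = c(1, -1, 1)
      )
    ),
    nodes = data.frame(id = c(net$nodes$id, "z1", "z2"))
  )
  got <- count_paths(extra, "n1", "n8", 5)
  expect_equal(got$activatory, base$activatory)
  expect_equal(got$inhibitory, base$inhibitory)
})

test_that("DP evaluates at most |V| * (lmax + 1) states", {
  for (seed in 1:10) {
    n <- 8 + seed
    net <- random_signed_network(n, p = 0.4, seed = 400 + seed)
    lmax <- 6
    cp <- count_paths(net, "n1", paste0("n", n), lmax, variant = "all")
    states <- attr(cp, "states")
    expect_true(is.finite(states))
    expect_lte(states, n * (lmax + 1))
  }
})

test_that("counts are independent of edge insertion order", {
  net <- random_signed_network(9, p = 0.4, seed = 31)
  shuffled <- withr::with_seed(99, {
    signed_network(net$edges[sample(nrow(net$edges)), ], net$nodes)
  })
  for (v in c("all", "simple")) {
    expect_equal(
      count_paths(net, "n1", "n9", 5, variant = v)$total,
      count_paths(shuffled, "n1", "n9", 5, variant = v)$total
    )
  }
})

test_that("opposite-polarity parallel edges are both counted", {
  net <- signed_network(data.frame(
    from = c("s", "a", "a"), to = c("a", "t", "t"), polarity = c(1, 1, -1)
  ))
  for (v in c("all", "simple")) {
    cp <- count_paths(net, "s", "t", 2, variant = v)
    expect_equal(cp$activatory, 1, label = v)
    expect_equal(cp$inhibitory, 1, label = v)
  }
})

test_that("delta invariants hold: directions sum to one, normalization", {
  counts <- data.frame(activatory = c(3, 0, 5), inhibitory = c(3, 20, 0))
  inh <- effect_score(counts, "inhibition")
  act <- effect_score(counts, "activation")
  expect_equal(inh$delta + act$delta, rep(1, 3))
  expect_equal(inh$normalized_score, c(0, -1, 1))
  expect_equal(effect_score(data.frame(
    activatory = 0, inhibitory = 20
  ))$delta, 1)
  expect_equal(effect_score(data.frame(
    activatory = 1, inhibitory = 4
  ))$normalized_score, -0.6)
})
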