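fig_colors <- c("b", "a", "b", "c", "a", "d", "a", "c")

test_that("the printed eight-element instance has the printed optimum", {
  res <- mncp(fig_colors)
  expect_equal(res$k, 5L)
  expect_equal(res$classes, list(c(1L, 3L), 2L, c(4L, 8L), c(5L, 7L), 6L))
  expect_equal(brute_force_mncp(fig_colors), 5L)
  # the printed crossing partition is rejected, the optimal one accepted
  expect_false(is_noncrossing_colored(list(c(1, 3), c(2, 5, 7), c(4, 8), 6),
                                      fig_colors))
  expect_true(is_noncrossing_colored(list(c(1, 3), 2, c(4, 8), c(5, 7), 6),
                                     fig_colors))
  expect_true(is_noncrossing_colored(as.list(1:8), fig_colors))
})

test_that("degenerate colorings give the extreme cardinalities", {
  for (n in c(1, 2, 5, 9)) {
    mono <- mncp(rep("a", n))
    expect_equal(mono$k, 1L)
    expect_equal(mono$classes, list(seq_len(n)))
  }
  dist6 <- mncp(letters[1:6])
  expect_equal(dist6$k, 6L)
  expect_equal(brute_force_mncp("q"), 1L)
  expect_equal(brute_force_mncp(c("a", "b", "a", "b")), 3L)
  expect_equal(mncp(c("a", "b", "a", "b"))$k, 3L)
})

test_that("the dynamic program equals brute force on random sequences", {
  for (s in 1:200) {
    set.seed(2000 + s)
    n <- 1 + (s %% 10)
    cols <- sample(letters[1:(1 + s %% 4)], n, replace = TRUE)
    res <- mncp(cols)
    expect_equal(res$k, brute_force_mncp(cols),
                 info = paste(cols, collapse = ","))
    expect_true(is_noncrossing_colored(res$classes, cols))
    # bounds: distinct colors <= k <= n
    expect_gte(res$k, length(unique(cols)))
    expect_lte(res$k, n)
    # appending a fresh color adds exactly one class
    expect_equal(mncp(c(cols, "zz"))$k, res$k + 1L)
  }
})

test_that("cardinality is rotation invariant for cycle-origin sequences", {
  for (s in 1:40) {
    set.seed(2500 + s)
    n <- 2 + (s %% 8)
    cols <- sample(letters[1:(1 + s %% 4)], n, replace = TRUE)
    k <- mncp(cols)$k
    for (r in seq_len(n - 1)) {
      expect_equal(mncp(cols[c((r + 1):n, 1:r)])$k, k)
    }
  }
})

test_that("component sequences follow the traversal order", {
  w <- worked_example()
  g <- build_graph(w$a, w$b, w$col)
  cyc <- Filter(function(cp) cp$kind == "cycle", g$components)[[1]]
  sq <- component_sequence(cyc)
  expect_equal(length(sq$colors), 2)
  expect_setequal(cyc$a_edges$adjacency, c("1h-5h", "2t-6t"))
  expect_true(sq$circular)
  aa <- Filter(function(cp) cp$kind == "AA_path", g$components)[[1]]
  expect_equal(length(component_sequence(aa)$colors), 2)
  expect_false(component_sequence(aa)$circular)
  odd1 <- Filter(function(cp) cp$kind == "odd_path", g$components)
  expect_true(all(vapply(odd1, function(cp) cp$n_a >= 1, logical(1))))
})

test_that("partition splits realize the classes as separate components", {
  # trivial: a monochromatic component needs no splits
  w <- worked_example()
  g <- build_graph(w$a, w$b, w$col)
  cyc <- Filter(function(cp) cp$kind == "cycle", g$components)[[1]]
  mono_classes <- list(seq_len(cyc$n_a))
  if (length(unique(cyc$a_edges$color)) == 1) {
    expect_length(partition_to_splits(cyc, mono_classes), 0)
  }

  # a 2-A-edge cycle with two colors: the single split separates them
  inst <- single_cycle8_instance(fig_colors)
  g8 <- build_graph(inst$a, inst$b, inst$col)
  comp <- g8$components[[1]]
  res <- mncp(component_sequence(comp))
  expect_equal(res$k, 5L)
  splits <- partition_to_splits(comp, res$classes)
  expect_length(splits, 4L)

  # replay the splits: the components of the resulting graph carry exactly
  # the class color multisets, each monochromatic
  adj <- genome_to_adjacencies(inst$a)
  colv <- unclass(inst$col)
  for (m in splits) {
    r <- grcs:::apply_move_adj(adj, colv, m)
    adj <- r$adj; colv <- r$col
  }
  g2 <- grcs:::ag_core(adj, genome_to_adjacencies(inst$b), colv)
  got <- sort(vapply(g2$components, function(cp)
    paste(sort(cp$a_edges$color), collapse = ""), character(1)))
  want <- sort(vapply(res$classes, function(cl)
    paste(sort(fig_colors[cl]), collapse = ""), character(1)))
  expect_identical(got, want)
  expect_true(all(vapply(g2$components, function(cp)
    length(unique(cp$a_edges$color)) == 1, logical(1))))

  # rejects partitions that are not noncrossing colored for the component
  expect_error(partition_to_splits(comp, list(c(1L, 2L), seq(3L, 8L))),
               class = "grcs_invalid_partition")
})

test_that("split moves are sorting moves and keep intermediates noncrossing", {
  for (s in 1:25) {
    inst <- random_instance(s, scramble_offset = 1L, seed_base = 2600L)
    g <- build_graph(inst$a, inst$b, inst$col)
    adj <- genome_to_adjacencies(inst$a)
    adjB <- genome_to_adjacencies(inst$b)
    colv <- unclass(inst$col)
    d <- dcj_distance(inst$a, inst$b)
    for (cp in g$components) {
      res <- mncp(component_sequence(cp))
      if (res$k == 1) next
      splits <- partition_to_splits(cp, res$classes, check = TRUE)
      expect_length(splits, res$k - 1)
      for (m in splits) {
        r <- grcs:::apply_move_adj(adj, colv, m)
        adj <- r$adj; colv <- r$col
        g2 <- grcs:::ag_core(adj, adjB)
        expect_equal(g2$N - (g2$C + g2$I / 2), d - 1)
        d <- d - 1
      }
    }
  }
})
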