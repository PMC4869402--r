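test_that("instance generation is reproducible and reachable", {
  i1 <- random_genome_pair(5, 2, 1, n_colors = 3, scramble_moves = 4, seed = 5)
  i2 <- random_genome_pair(5, 2, 1, n_colors = 3, scramble_moves = 4, seed = 5)
  expect_identical(write_genomes(i1$a), write_genomes(i2$a))
  expect_identical(write_genomes(i1$b), write_genomes(i2$b))
  expect_identical(unclass(i1$col), unclass(i2$col))

  i0 <- random_genome_pair(4, 1, 0, scramble_moves = 0, seed = 9)
  expect_equal(dcj_distance(i0$a, i0$b), 0L)

  for (s in 1:10) {
    inst <- random_genome_pair(4 + s %% 3, 1 + s %% 2, s %% 2,
                               scramble_moves = s, seed = s)
    expect_true(validate_equal_content(inst$a, inst$b))
  }
  expect_error(random_genome_pair(2, 2, 1, seed = 1), class = "grcs_size_guard")
})

test_that("the rare-move oracle is invariant under relabeling", {
  inst <- random_genome_pair(4, 2, 0, n_colors = 2, scramble_moves = 3,
                             seed = 31)
  bf <- brute_force_min_rare(inst$a, inst$b, inst$col)

  relabel <- function(g, perm) {
    genome(lapply(g$chromosomes, function(ch) {
      list(blocks = sign(ch$blocks) * perm[abs(ch$blocks)],
           circular = ch$circular)
    }), name = g$name)
  }
  perm <- c(3L, 1L, 4L, 2L)
  a2 <- relabel(inst$a, perm)
  map_adj <- function(adj) {
    ends <- strsplit(adj, "-", fixed = TRUE)[[1]]
    ends <- vapply(ends, function(e) {
      if (e == "$") return("$")
      paste0(perm[as.integer(sub("[ht]$", "", e))], substring(e, nchar(e)))
    }, character(1))
    adjacency(ends[1], ends[2])
  }
  cols <- unclass(inst$col)
  names(cols) <- vapply(names(cols), map_adj, character(1))
  # permute the color symbols too
  cols[] <- chartr("abcd", "badc", cols)
  col2 <- color_map(cols, a2)
  expect_equal(brute_force_min_rare(a2, relabel(inst$b, perm), col2), bf)
})

test_that("oracle and formula agree on a no-even-path multi-component instance", {
  # two cycles with known partition cardinalities: rare = (k1-1) + (k2-1)
  a <- genome(list(list(blocks = 1:2, circular = TRUE),
                   list(blocks = 3:4, circular = TRUE)), name = "A")
  b <- genome(list(list(blocks = c(1, -2), circular = TRUE),
                   list(blocks = c(3, -4), circular = TRUE)), name = "B")
  g0 <- build_graph(a, b)
  expect_true(all(vapply(g0$components, classify_component,
                         character(1)) == "cycle"))
  cols <- stats::setNames(c("a", "b", "c", "d"), genome_to_adjacencies(a))
  col <- color_map(cols, a)
  g <- build_graph(a, b, col)
  ks <- vapply(g$components, function(cp) mncp(component_sequence(cp))$k,
               integer(1))
  expect_equal(brute_force_min_rare(a, b, col), sum(ks - 1L))
  expect_equal(min_rare_count(a, b, col), sum(ks - 1L))
})

test_that("a 4-A-edge alternating cycle needs two rare moves", {
  pair <- single_cycle_instance(4)
  g0 <- build_graph(pair$a, pair$b)
  comp <- g0$components[[1]]
  cols <- stats::setNames(rep("", 4), comp$a_edges$adjacency)
  cols[] <- c("a", "b", "a", "b")
  col <- color_map(cols, pair$a)
  expect_equal(brute_force_min_rare(pair$a, pair$b, col), 2L)
  expect_equal(min_rare_count(pair$a, pair$b, col), 2L)
})

test_that("scenario enumeration matches direct counts", {
  # d = 0: exactly one empty scenario
  a <- lin_genome(c(1, 2), name = "A")
  expect_length(enumerate_parsimonious_scenarios(a, a), 1)
  expect_length(enumerate_parsimonious_scenarios(a, a)[[1]], 0)

  # d = 1: scenarios are exactly the sorting moves
  b <- lin_genome(c(-1, 2), name = "B")
  sc <- enumerate_parsimonious_scenarios(a, b)
  ms <- enumerate_sorting_moves(a, b)
  expect_length(sc, length(ms))
  expect_setequal(vapply(sc, function(s) grcs:::move_key(s[[1]]), character(1)),
                  vapply(ms, grcs:::move_key, character(1)))

  # single cycles: counts match the independent split-tree recursion
  for (m in 2:4) {
    pair <- single_cycle_instance(m)
    expect_length(enumerate_parsimonious_scenarios(pair$a, pair$b),
                  cycle_scenario_count(m))
  }

  # every enumerated scenario verifies
  inst <- random_genome_pair(4, 2, 0, n_colors = 2, scramble_moves = 2,
                             seed = 77)
  for (sc in enumerate_parsimonious_scenarios(inst$a, inst$b)) {
    adj <- genome_to_adjacencies(inst$a)
    d <- dcj_distance(inst$a, inst$b)
    okd <- TRUE
    for (m in sc) {
      adj <- c(setdiff(adj, m$cut), m$rejoin)
      g2 <- grcs:::ag_core(adj, genome_to_adjacencies(inst$b))
      d2 <- g2$N - (g2$C + g2$I / 2)
      okd <- okd && (d2 == d - 1)
      d <- d2
    }
    expect_true(okd)
    expect_setequal(adj, genome_to_adjacencies(inst$b))
  }
})
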