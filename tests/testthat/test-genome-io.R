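test_that("parsing recovers the printed adjacency sets", {
  gs <- parse_genomes("> A\n5 -1 -2 6 -4 -8 $\n-3 7 $\n9 10 @")
  a <- gs[["A"]]
  expect_setequal(genome_to_adjacencies(a),
                  c("5t-$", "1h-5h", "1t-2h", "2t-6t", "4h-6h", "4t-8h",
                    "8t-$", "3h-$", "3t-7t", "7h-$", "9h-10t", "9t-10h"))
  expect_equal(n_blocks(a), 10)

  circ <- parse_genomes("> C\n9 10 @")[[1]]
  expect_setequal(genome_to_adjacencies(circ), c("9h-10t", "9t-10h"))

  tiny <- parse_genomes("> T\n1 $")[[1]]
  expect_setequal(genome_to_adjacencies(tiny), c("1t-$", "1h-$"))
})

test_that("parse errors are distinct and message-bearing", {
  expect_error(parse_genomes("> A\n1 2 1 $"), class = "grcs_duplicate_block")
  expect_error(parse_genomes("> A\n1 x $"), class = "grcs_malformed_token")
  expect_error(parse_genomes("> A\n1 2"), class = "grcs_missing_terminator")
  expect_error(parse_genomes("> A\n$"), class = "grcs_empty_chromosome")
  expect_error(parse_genomes("1 2 $"), class = "grcs_malformed_token")
})

test_that("chromosome <-> adjacency conversion matches the printed forms", {
  g <- lin_genome(c(-3, 7))
  expect_setequal(genome_to_adjacencies(g), c("3h-$", "3t-7t", "7h-$"))
  expect_setequal(genome_to_adjacencies(lin_genome(c(1, 2))),
                  c("1t-$", "1h-2t", "2h-$"))

  back <- adjacencies_to_genome(c("1t-$", "1h-2t", "2h-$"))
  expect_equal(back$chromosomes[[1]]$blocks, c(1L, 2L))
  expect_false(back$chromosomes[[1]]$circular)

  one <- adjacencies_to_genome("1h-1t")
  expect_true(one$chromosomes[[1]]$circular)
  expect_equal(one$chromosomes[[1]]$blocks, 1L)

  worked <- worked_example()
  rebuilt <- adjacencies_to_genome(genome_to_adjacencies(worked$a))
  sizes <- sort(vapply(rebuilt$chromosomes, function(ch) length(ch$blocks),
                       integer(1)))
  expect_equal(sizes, c(2L, 6L))

  expect_error(adjacencies_to_genome(c("1t-$", "1h-2t")),
               class = "grcs_structural_error")
})

test_that("round trips and the adjacency-count law hold on random genomes", {
  for (s in 1:40) {
    nl <- s %% 3; nc <- s %% 2
    if (nl + nc == 0) nl <- 1
    inst <- random_genome_pair(max(nl + nc, 2 + s %% 5), nl, nc,
                               n_colors = 1 + s %% 4,
                               scramble_moves = s %% 6, seed = s)
    for (g in list(inst$a, inst$b)) {
      adj <- genome_to_adjacencies(g)
      expect_setequal(genome_to_adjacencies(parse_genomes(write_genomes(g))[[1]]),
                      adj)
      expect_setequal(genome_to_adjacencies(adjacencies_to_genome(adj)), adj)
      nlin <- sum(!vapply(g$chromosomes, function(ch) ch$circular, logical(1)))
      expect_length(adj, n_blocks(g) + nlin)
      expect_false(anyDuplicated(adj) > 0)
    }
  }
})

test_that("color maps are total, validated and round-trip through TSV", {
  w <- worked_example()
  expect_length(color_alphabet(w$col), 4)
  expect_equal(unname(unclass(w$col)["3t-7t"]), "a")

  g <- lin_genome(c(1, 2))
  mono <- color_map(c(`1t-$` = "a", `1h-2t` = "a", `2h-$` = "a"), g)
  expect_equal(color_alphabet(mono), "a")

  expect_error(color_map(c(`1t-$` = "a", `1h-2t` = "a"), g),
               regexp = "uncolored adjacency", class = "grcs_color_error")
  expect_error(color_map(c(`1t-$` = "a", `1h-2t` = "a", `2h-$` = "a",
                           `9h-9t` = "a"), g),
               class = "grcs_color_error")
  expect_error(parse_color_map(c("adjacency\tcolor", "1t-$\ta", "1t-$\tb",
                                 "1h-2t\ta", "2h-$\ta"), g),
               regexp = "duplicate", class = "grcs_color_error")

  rt <- parse_color_map(write_color_map(w$col), w$a)
  expect_identical(unclass(rt), unclass(w$col))
})

test_that("equal-content validation names the symmetric difference", {
  w <- worked_example()
  expect_true(validate_equal_content(w$a, w$b))
  expect_true(validate_equal_content(w$a, w$a))
  g1 <- lin_genome(c(1, 2)); g2 <- lin_genome(c(1, 3))
  expect_error(validate_equal_content(g1, g2), regexp = "\\{2,3\\}",
               class = "grcs_content_mismatch")
})

test_that("canonical adjacency strings are unique and deterministically ordered", {
  expect_equal(adjacency("5h", "1h"), "1h-5h")
  expect_equal(adjacency("$", "5t"), "5t-$")
  expect_equal(adjacency("2t", "2h"), "2h-2t")
  expect_error(adjacency("$", "$"), class = "grcs_invalid_adjacency")
  expect_error(adjacency("3h", "3h"), class = "grcs_invalid_adjacency")
  # distinct adjacencies never render to the same string
  g <- random_genome_pair(6, 2, 1, seed = 99)$a
  adj <- genome_to_adjacencies(g)
  expect_equal(anyDuplicated(adj), 0L)
})
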