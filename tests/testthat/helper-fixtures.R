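# Shared fixtures: the worked example genomes, small constructed components
# and instance generators used across the suite.

worked_example <- function() {
  a <- parse_genomes(readLines(system.file("extdata", "worked_A.txt",
                                           package = "grcs")))[[1]]
  b <- parse_genomes(readLines(system.file("extdata", "worked_B.txt",
                                           package = "grcs")))[[1]]
  col <- parse_color_map(readLines(system.file("extdata",
                                               "worked_A_colors_synthetic.tsv",
                                               package = "grcs")), a)
  list(a = a, b = b, col = col)
}

# a linear genome from a plain block vector
lin_genome <- function(..., name = NULL) {
  genome(lapply(list(...), function(b) list(blocks = b, circular = FALSE)),
         name = name)
}

# a free-standing path component carrying given A-edge colors (only the
# fields read by the mixing scorers are populated)
fake_path_component <- function(colors, kind) {
  n <- length(colors)
  structure(list(id = 0L, kind = kind, cross = character(0), length = 2L * n,
                 n_a = n, D = if (kind == "BB_path") n else n - 1L,
                 a_edges = data.frame(adjacency = paste0("x", seq_len(n)),
                                      first = paste0("u", seq_len(n)),
                                      second = paste0("v", seq_len(n)),
                                      color = colors,
                                      stringsAsFactors = FALSE)),
            class = "dcj_component")
}

# a genome pair whose adjacency graph is a single cycle with 8 A-edges,
# plus a color map writing the requested colors onto the A-edges in
# traversal order
single_cycle8_instance <- function(colors_in_order) {
  a <- genome(list(list(blocks = 1:8, circular = TRUE)), name = "A")
  b <- genome(list(list(blocks = c(-6, 4, -7, -1, 5, -8, -2, 3),
                        circular = TRUE)), name = "B")
  g0 <- build_graph(a, b)
  stopifnot(length(g0$components) == 1, g0$components[[1]]$n_a == 8)
  cols <- colors_in_order
  names(cols) <- g0$components[[1]]$a_edges$adjacency
  list(a = a, b = b, col = color_map(cols, a))
}

# first circular pair over m blocks whose graph is a single cycle with m
# A-edges (deterministic small search)
single_cycle_instance <- function(m) {
  a <- genome(list(list(blocks = seq_len(m), circular = TRUE)), name = "A")
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), m)))
  perms <- matrix(seq_len(m), nrow = 1)
  if (m > 1) {
    perms <- do.call(rbind, lapply(combinat_perms(seq_len(m)), rbind))
  }
  for (p in seq_len(nrow(perms))) {
    for (s in seq_len(nrow(signs))) {
      b <- genome(list(list(blocks = perms[p, ] * signs[s, ], circular = TRUE)),
                  name = "B")
      g <- build_graph(a, b)
      if (length(g$components) == 1 && g$components[[1]]$kind == "cycle" &&
          g$components[[1]]$n_a == m) {
        return(list(a = a, b = b))
      }
    }
  }
  stop("no single-cycle pair found")
}

combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# independent recursive count of parsimonious scenarios sorting one cycle
# with m A-edges: a first move splits the cycle into arcs of sizes s and
# m-s (m-s pairs of cut edges realize gap s), and the two sub-scenarios
# interleave freely
cycle_scenario_count <- function(m) {
  if (m <= 1) return(1)
  total <- 0
  for (s in 1:(m - 1)) {
    total <- total + (m - s) * cycle_scenario_count(s) *
      cycle_scenario_count(m - s) * choose(m - 2, s - 1)
  }
  total
}

random_instance <- function(s, scramble_offset = 0L, seed_base = 0L) {
  nb <- 2L + (s %% 4L)
  random_genome_pair(nb,
                     n_linear = 1L + (s %% 2L), n_circular = s %% 2L,
                     n_colors = 1L + (s %% 4L),
                     scramble_moves = scramble_offset + (s %% 4L),
                     seed = seed_base + s)
}
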