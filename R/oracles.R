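# ---------------------------------------------------------------------------
# Seeded random instances and exhaustive brute-force solvers used as ground
# truth in tests.  The brute-force solvers work directly on adjacency
# string sets; canonical state keys collapse the search space.
# ---------------------------------------------------------------------------

adjset_key <- function(adjset) paste(str_sort(adjset), collapse = ";")

colored_key <- function(adjset, colvec) {
  paste(str_sort(paste0(adjset, "=", unlist(colvec[adjset]))), collapse = ";")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# every syntactically possible DCJ on an adjacency set, as cut/rejoin lists
syntactic_moves_adj <- function(adjset) {
  n <- length(adjset)
  ends <- lapply(adjset, adj_ends)
  moves <- list()
  push <- function(cut, rejoin) {
    rejoin <- rejoin[rejoin != paste0(TELOMERE, "-", TELOMERE)]
    if (length(rejoin) == 0) return()
    if (setequal(rejoin, cut)) return()  # no-op reglueing
    moves[[length(moves) + 1L]] <<- list(cut = cut, rejoin = rejoin)
  }
  mk <- function(u, v) {
    if (u == TELOMERE && v == TELOMERE) return(paste0(TELOMERE, "-", TELOMERE))
    adjacency(u, v)
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        u <- ends[[i]][1]; v <- ends[[i]][2]
        x <- ends[[j]][1]; y <- ends[[j]][2]
        cut <- c(adjset[i], adjset[j])
        push(cut, c(mk(u, x), mk(v, y)))
        push(cut, c(mk(u, y), mk(v, x)))
      }
    }
  }
  for (i in seq_len(n)) {
    if (!any(ends[[i]] == TELOMERE)) {
      push(adjset[i], c(adjacency(ends[[i]][1], TELOMERE),
                        adjacency(ends[[i]][2], TELOMERE)))
    }
  }
  moves
}

#' All syntactically possible DCJ moves on a genome
#'
#' Used as the exhaustive oracle against which the structural enumeration
#' of sorting moves is checked.
#'
#' @param g a `genome`.
#' @return list of `dcj_move` objects (without color assignments).
#' @export
syntactic_moves <- function(g) {
  lapply(syntactic_moves_adj(genome_to_adjacencies(g)),
         function(m) dcj_move(m$cut, m$rejoin))
}

#' Breadth-first-search DCJ distance (oracle)
#'
#' Explores the genome space by applying every syntactic DCJ, independent
#' of the adjacency-graph distance formula.
#'
#' @param a,b `genome` objects with equal block content.
#' @param max_depth search guard.
#' @return shortest number of DCJs turning `a` into `b`.
#' @export
bfs_dcj_distance <- function(a, b, max_depth = 8L) {
  validate_equal_content(a, b)
  target <- adjset_key(genome_to_adjacencies(b))
  frontier <- list(genome_to_adjacencies(a))
  if (adjset_key(frontier[[1]]) == target) return(0L)
  seen <- new.env(parent = emptyenv())
  assign(adjset_key(frontier[[1]]), TRUE, envir = seen)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      for (m in syntactic_moves_adj(st)) {
        st2 <- c(setdiff(st, m$cut), m$rejoin)
        key <- adjset_key(st2)
        if (key == target) return(as.integer(depth))
        if (!exists(key, envir = seen)) {
          assign(key, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- st2
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  grcs_abort(sprintf("BFS did not reach the target within depth %d", max_depth),
             "grcs_size_guard")
}

#' Generate a seeded random genome pair with a random coloring
#'
#' Genome B is a uniformly random arrangement of the blocks over the
#' requested chromosomes; genome A is produced from B by `scramble_moves`
#' random DCJs (so every instance is reachable); colors are drawn uniformly
#' over `n_colors` symbols for all adjacencies of A.
#'
#' @param n_blocks number of blocks (>= number of chromosomes).
#' @param n_linear,n_circular chromosome counts of B (at least one in
#'   total).
#' @param n_colors size of the color alphabet (symbols `a`, `b`, ...).
#' @param scramble_moves number of random DCJs applied to derive A.
#' @param seed integer seed; the pair is fully reproducible from it.
#' @return list with `a`, `b` (genomes) and `col` (a `color_map` for `a`).
#' @export
random_genome_pair <- function(n_blocks, n_linear = 1L, n_circular = 0L,
                               n_colors = 2L, scramble_moves = n_blocks,
                               seed = 1L) {
  n_chrom <- n_linear + n_circular
  if (!(n_blocks >= n_chrom && n_chrom >= 1 && n_colors >= 1))
    grcs_abort("infeasible instance spec", "grcs_size_guard")
  with_seed(seed, {
    perm <- sample(n_blocks) * sample(c(-1L, 1L), n_blocks, replace = TRUE)
    cuts <- if (n_chrom > 1) sort(sample(n_blocks - 1L, n_chrom - 1L)) else integer(0)
    bounds <- c(0L, cuts, n_blocks)
    chroms <- lapply(seq_len(n_chrom), function(i) {
      list(blocks = perm[(bounds[i] + 1L):bounds[i + 1L]],
           circular = i > n_linear)
    })
    b <- genome(chroms, name = "B")
    adj <- genome_to_adjacencies(b)
    if (scramble_moves > 0) {
      for (s in seq_len(scramble_moves)) {
        cand <- syntactic_moves_adj(adj)
        m <- cand[[sample(length(cand), 1L)]]
        adj <- c(setdiff(adj, m$cut), m$rejoin)
      }
    }
    a <- adjacencies_to_genome(adj, name = "A")
    adjA <- genome_to_adjacencies(a)
    cols <- sample(letters[seq_len(n_colors)], length(adjA), replace = TRUE)
    names(cols) <- adjA
    list(a = a, b = b, col = color_map(cols, a))
  })
}

#' Brute-force minimum number of rare moves (oracle)
#'
#' Depth-first search over sorting moves, trying both color routings of
#' every rare move, memoized on the colored genome state.  Exact but
#' exponential; guarded to small instances.
#'
#' @param a,b `genome` objects with equal block content.
#' @param col a `color_map` for `a`.
#' @param max_blocks,max_d size guards.
#' @return exact minimum total weight over all parsimonious scenarios.
#' @export
brute_force_min_rare <- function(a, b, col, max_blocks = 6L, max_d = 7L) {
  validate_equal_content(a, b)
  if (n_blocks(a) > max_blocks)
    grcs_abort("brute_force_min_rare is limited to small genomes",
               "grcs_size_guard")
  if (dcj_distance(a, b) > max_d)
    grcs_abort("brute_force_min_rare is limited to small distances",
               "grcs_size_guard")
  adjB <- genome_to_adjacencies(b)
  targ <- adjset_key(adjB)
  memo <- new.env(parent = emptyenv())
  rec <- function(adjset, colvec) {
    if (adjset_key(adjset) == targ) return(0L)
    key <- colored_key(adjset, colvec)
    if (exists(key, envir = memo)) return(get(key, envir = memo))
    graph <- ag_core(adjset, adjB, colvec)
    best <- Inf
    for (m in moves_from_graph(graph)) {
      w <- if (length(m$cut) == 2L)
        as.integer(colvec[[m$cut[1]]] != colvec[[m$cut[2]]]) else 0L
      assigns <- if (w == 1L && length(m$rejoin) == 2L) {
        c1 <- colvec[[m$cut[1]]]; c2 <- colvec[[m$cut[2]]]
        list(stats::setNames(c(c1, c2), m$rejoin),
             stats::setNames(c(c2, c1), m$rejoin))
      } else if (w == 1L) {
        # fusion absorbing telomeres: the surviving adjacency takes either color
        list(stats::setNames(colvec[[m$cut[1]]], m$rejoin),
             stats::setNames(colvec[[m$cut[2]]], m$rejoin))
      } else {
        list(NULL)
      }
      for (as_ in assigns) {
        m2 <- if (is.null(as_)) m else dcj_move(m$cut, m$rejoin, colors = as_)
        res <- apply_move_adj(adjset, colvec, m2)
        v <- w + rec(res$adj, res$col)
        if (v < best) best <- v
      }
    }
    best <- as.integer(best)
    assign(key, best, envir = memo)
    best
  }
  rec(genome_to_adjacencies(a), unclass(col))
}

#' Enumerate every parsimonious scenario (oracle)
#'
#' Yields every distinct sequence of sorting moves turning `a` into `b`
#' (genome-level; color routings are not expanded).  Guarded to tiny
#' instances.
#'
#' @param a,b `genome` objects with equal block content.
#' @param max_d size guard on the distance.
#' @return list of scenarios, each a list of `dcj_move` objects.
#' @export
enumerate_parsimonious_scenarios <- function(a, b, max_d = 5L) {
  validate_equal_content(a, b)
  if (dcj_distance(a, b) > max_d)
    grcs_abort("enumerate_parsimonious_scenarios is limited to small distances",
               "grcs_size_guard")
  adjB <- genome_to_adjacencies(b)
  out <- list()
  rec <- function(adjset, prefix) {
    graph <- ag_core(adjset, adjB)
    ms <- moves_from_graph(graph)
    if (length(ms) == 0) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (m in ms) {
      rec(c(setdiff(adjset, m$cut), m$rejoin), c(prefix, list(m)))
    }
  }
  rec(genome_to_adjacencies(a), list())
  out
}
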