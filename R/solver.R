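# ---------------------------------------------------------------------------
# Assembling a Minimum Local Parsimonious Scenario:
#   (i)  one mixing move per matched AA/BB pair,
#   (ii) k-1 partition splits per component,
#   (iii) likely completion moves sorting each monochromatic component.
# Every emitted move is a sorting move, so the scenario length is the DCJ
# distance by construction; the realized total weight is asserted to equal
# the matching-based optimum.
# ---------------------------------------------------------------------------

#' Minimum number of rare moves in a parsimonious scenario
#'
#' Computes `d - (likely on non-even components + optimal mixing total)`:
#' every component contributes `D - (k - 1)` likely moves on its own, and
#' the bipartite matching decides which even-path pairs gain likely moves
#' by being mixed.
#'
#' @param a,b `genome` objects with equal block content.
#' @param col a `color_map` over the adjacencies of `a`.
#' @return non-negative integer.
#' @export
min_rare_count <- function(a, b, col) {
  graph <- build_graph(a, b, col)
  d <- graph$N - (graph$C + graph$I / 2)
  noneven <- Filter(function(cp) cp$kind %in% c("cycle", "odd_path"),
                    graph$components)
  likely_noneven <- sum(vapply(noneven, likely_count, integer(1)))
  om <- optimal_mixing(build_mix_graph(graph$components))
  as.integer(d - (likely_noneven + om$total))
}

# pick the best (i, j, case) realization of a mixing move for a matched pair
best_mix_realization <- function(p, q) {
  e <- p$a_edges$color; f <- q$a_edges$color
  best <- NULL
  for (i in seq_along(e)) {
    for (j in seq_along(f)) {
      w <- as.integer(e[i] != f[j])
      for (case in 1:4) {
        ps <- mix_case_sequences(e, f, i, j, case)
        rare <- w + (mncp(ps$p1)$k - 1L) + (mncp(ps$p2)$k - 1L)
        if (is.null(best) || rare < best$rare) {
          best <- list(i = i, j = j, case = case, rare = rare, w = w)
        }
      }
    }
  }
  best
}

mix_move_from_realization <- function(p, q, r) {
  i <- r$i; j <- r$j
  a <- p$a_edges$first[i];  b <- p$a_edges$second[i]
  c_ <- q$a_edges$first[j]; d <- q$a_edges$second[j]
  ce <- p$a_edges$color[i]; cf <- q$a_edges$color[j]
  rj <- switch(r$case,
               c(adjacency(a, c_), adjacency(b, d)),
               c(adjacency(a, c_), adjacency(b, d)),
               c(adjacency(a, d), adjacency(b, c_)),
               c(adjacency(a, d), adjacency(b, c_)))
  cols <- switch(r$case, c(ce, cf), c(cf, ce), c(ce, cf), c(cf, ce))
  names(cols) <- rj
  dcj_move(c(p$a_edges$adjacency[i], q$a_edges$adjacency[j]), rj, colors = cols)
}

# canonical likely move finishing one step of a monochromatic component
completion_move <- function(cp) {
  ae <- cp$a_edges
  if (cp$kind == "BB_path") {
    rj <- c(adjacency(ae$first[1], TELOMERE), adjacency(ae$second[1], TELOMERE))
    cols <- rep(ae$color[1], length(rj)); names(cols) <- rj
    return(dcj_move(ae$adjacency[1], rj, colors = cols))
  }
  rj <- split_rejoin(ae, 1L, 2L)
  cols <- if (length(rj) == 2) c(ae$color[1], ae$color[2]) else ae$color[1]
  names(cols) <- rj
  dcj_move(c(ae$adjacency[1], ae$adjacency[2]), rj, colors = cols)
}

#' Sort one genome into another with a minimum number of rare moves
#'
#' Emits a full parsimonious scenario: mixing moves for the matched
#' even-path pairs first, then the MNCP partition splits of every
#' component, then likely completion moves.  The scenario is verified
#' internally: its length must equal the DCJ distance and its total weight
#' must equal [min_rare_count()]; any discrepancy raises an internal
#' assertion error.
#'
#' @param a,b `genome` objects with equal block content.
#' @param col a `color_map` over the adjacencies of `a`.
#' @return object of class `sort_result` with fields `scenario` (class
#'   `dcj_scenario`: `moves`, `weights`, `total_weight`, `length`),
#'   `min_rare`, `partitions` (per post-mix component) and `matching`.
#' @export
sort_genomes <- function(a, b, col) {
  validate_equal_content(a, b)
  adjB <- genome_to_adjacencies(b)
  cur <- genome_to_adjacencies(a)
  colvec <- unclass(color_map(unclass(col), a))
  d0 <- dcj_distance(a, b)
  target_rare <- min_rare_count(a, b, col)

  moves <- list(); weights <- integer(0)
  emit <- function(m) {
    w <- if (length(m$cut) == 2L)
      as.integer(colvec[[m$cut[1]]] != colvec[[m$cut[2]]]) else 0L
    res <- apply_move_adj(cur, colvec, m)
    cur <<- res$adj; colvec <<- res$col
    moves[[length(moves) + 1L]] <<- m
    weights <<- c(weights, w)
  }

  # (i) mixing
  graph <- ag_core(cur, adjB, colvec)
  om <- optimal_mixing(build_mix_graph(graph$components))
  if (nrow(om$pairs)) {
    comp_by_id <- graph$components
    for (r in seq_len(nrow(om$pairs))) {
      p <- comp_by_id[[om$pairs$p[r]]]
      q <- comp_by_id[[om$pairs$q[r]]]
      emit(mix_move_from_realization(p, q, best_mix_realization(p, q)))
    }
  }

  # (ii) partition splits
  graph <- ag_core(cur, adjB, colvec)
  partitions <- list()
  for (cp in graph$components) {
    res <- mncp(component_sequence(cp))
    partitions[[length(partitions) + 1L]] <-
      list(component = cp$id, kind = cp$kind, k = res$k, classes = res$classes)
    if (res$k > 1) {
      for (m in partition_to_splits(cp, res$classes)) emit(m)
    }
  }

  # (iii) likely completion
  repeat {
    if (length(moves) > d0)
      grcs_abort("scenario exceeded the DCJ distance (internal error)",
                 "grcs_internal")
    graph <- ag_core(cur, adjB, colvec)
    todo <- Filter(function(cp) cp$D > 0, graph$components)
    if (length(todo) == 0) break
    emit(completion_move(todo[[1]]))
  }

  if (!setequal(cur, adjB))
    grcs_abort("scenario did not reach the target genome (internal error)",
               "grcs_internal")
  if (length(moves) != d0)
    grcs_abort("scenario length differs from the DCJ distance (internal error)",
               "grcs_internal")
  if (sum(weights) != target_rare)
    grcs_abort(sprintf(paste0("realized scenario weight (%d) differs from the ",
                              "matching optimum (%d) (internal error)"),
                       sum(weights), target_rare),
               "grcs_internal")

  scenario <- structure(list(moves = moves, weights = weights,
                             total_weight = as.integer(sum(weights)),
                             length = length(moves)),
                        class = "dcj_scenario")
  structure(list(scenario = scenario, min_rare = target_rare,
                 partitions = partitions, matching = om$pairs),
            class = "sort_result")
}

#' @export
print.dcj_scenario <- function(x, ...) {
  cat(sprintf("DCJ scenario: %d move(s), total weight %d\n",
              x$length, x$total_weight))
  invisible(x)
}

#' @export
print.sort_result <- function(x, ...) {
  print(x$scenario)
  cat(sprintf("minimum rare moves: %d; mixed pairs: %d\n",
              x$min_rare, nrow(x$matching)))
  invisible(x)
}

#' Tabulate a scenario
#'
#' @param s a `dcj_scenario`.
#' @return data frame with columns step, cut1, cut2, new1, new2, weight,
#'   color1, color2 (`"-"` for absent fields; colors are those assigned to
#'   new1/new2).
#' @export
scenario_table <- function(s) {
  n <- s$length
  row <- function(i) {
    m <- s$moves[[i]]
    cols <- if (is.null(m$colors)) rep("-", length(m$rejoin)) else unname(m$colors)
    data.frame(step = i,
               cut1 = m$cut[1], cut2 = if (length(m$cut) > 1) m$cut[2] else "-",
               new1 = m$rejoin[1],
               new2 = if (length(m$rejoin) > 1) m$rejoin[2] else "-",
               weight = s$weights[i],
               color1 = cols[1],
               color2 = if (length(cols) > 1) cols[2] else "-",
               stringsAsFactors = FALSE)
  }
  if (n == 0) {
    return(data.frame(step = integer(0), cut1 = character(0),
                      cut2 = character(0), new1 = character(0),
                      new2 = character(0), weight = integer(0),
                      color1 = character(0), color2 = character(0)))
  }
  do.call(rbind, lapply(seq_len(n), row))
}

#' Verify a scenario against its endpoints, weights and colors
#'
#' Replays the scenario from `a`, checking that every move cuts existing
#' adjacencies, reduces the DCJ distance to `b` by exactly one, that the
#' recorded weights match the colors at application time, that untouched
#' adjacencies keep their colors, and that the final genome equals `b`.
#'
#' @param a,b `genome` objects.
#' @param col a `color_map` for `a`.
#' @param s a `dcj_scenario`.
#' @return list with `pass` (logical) and a named logical vector `checks`
#'   (`endpoint`, `sorting`, `weights`, `colors`) plus `messages`.
#' @export
verify_scenario <- function(a, b, col, s) {
  adjB <- genome_to_adjacencies(b)
  cur <- genome_to_adjacencies(a)
  colvec <- unclass(col)
  checks <- c(endpoint = TRUE, sorting = TRUE, weights = TRUE, colors = TRUE)
  msgs <- character(0)
  dist_of <- function(adjset) {
    g <- ag_core(adjset, adjB)
    g$N - (g$C + g$I / 2)
  }
  d <- dist_of(cur)
  for (i in seq_along(s$moves)) {
    m <- s$moves[[i]]
    if (!all(m$cut %in% cur)) {
      checks["sorting"] <- FALSE
      msgs <- c(msgs, sprintf("step %d cuts a missing adjacency", i))
      break
    }
    w <- if (length(m$cut) == 2L)
      as.integer(colvec[[m$cut[1]]] != colvec[[m$cut[2]]]) else 0L
    if (!identical(as.integer(w), as.integer(s$weights[i]))) {
      checks["weights"] <- FALSE
      msgs <- c(msgs, sprintf("step %d recorded weight %d, recomputed %d",
                              i, s$weights[i], w))
    }
    untouched <- setdiff(cur, m$cut)
    res <- apply_move_adj(cur, colvec, m)
    if (!identical(colvec[untouched], res$col[untouched])) {
      checks["colors"] <- FALSE
      msgs <- c(msgs, sprintf("step %d changed the color of an untouched adjacency", i))
    }
    cur <- res$adj; colvec <- res$col
    d2 <- dist_of(cur)
    if (d2 != d - 1) {
      checks["sorting"] <- FALSE
      msgs <- c(msgs, sprintf("step %d changes the distance by %d", i, d2 - d))
    }
    d <- d2
  }
  if (!setequal(cur, adjB)) {
    checks["endpoint"] <- FALSE
    msgs <- c(msgs, "scenario does not end at the target genome")
  }
  list(pass = all(checks), checks = checks, messages = msgs)
}
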