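# ---------------------------------------------------------------------------
# DCJ moves: cut one or two adjacencies of the current genome and reglue.
#
# A move stores the cut adjacencies, the resulting adjacencies and an
# optional color assignment routing the colors of the cut edges onto the
# results (both routings are legal for the same genome outcome; the solver
# sets them explicitly, elsewhere a deterministic default is used).
# ---------------------------------------------------------------------------

#' Construct a DCJ move
#'
#' @param cut character vector of one or two canonical adjacency strings to
#'   cut.
#' @param rejoin character vector of one or two resulting adjacency strings
#'   (a degenerate `$-$` product of a fusion is omitted).
#' @param colors optional named character vector assigning a color to each
#'   rejoin adjacency; when `NULL` a deterministic default is derived at
#'   application time.
#' @return an object of class `dcj_move`.
#' @export
dcj_move <- function(cut, rejoin, colors = NULL) {
  stopifnot(length(cut) %in% 1:2, length(rejoin) %in% 1:2)
  exts_of <- function(x) {
    e <- unlist(strsplit(x, "-", fixed = TRUE))
    str_sort(e[e != TELOMERE])
  }
  if (!identical(exts_of(cut), exts_of(rejoin)))
    grcs_abort("rejoin does not conserve the extremities of the cut",
               "grcs_invalid_move")
  if (!is.null(colors)) {
    if (!setequal(names(colors), rejoin))
      grcs_abort("color assignment must cover exactly the rejoin adjacencies",
                 "grcs_invalid_move")
    colors <- colors[rejoin]
  }
  structure(list(cut = unname(cut), rejoin = unname(rejoin), colors = colors),
            class = "dcj_move")
}

#' @export
print.dcj_move <- function(x, ...) {
  cat(sprintf("DCJ: cut {%s} -> rejoin {%s}\n",
              paste(x$cut, collapse = ", "), paste(x$rejoin, collapse = ", ")))
  invisible(x)
}

move_key <- function(m) {
  paste(paste(str_sort(m$cut), collapse = "+"),
        paste(str_sort(m$rejoin), collapse = "+"), sep = "|")
}

# smaller extremity of a canonical adjacency string (its first token)
adj_first_ext <- function(adj) adj_ends(adj)[1]

# default color routing: the result containing the canonically smaller
# extremity of the canonically smaller cut edge inherits that edge's color
default_color_assignment <- function(cut, rejoin, colvec) {
  cols <- vapply(cut, function(a) colvec[[a]], character(1))
  if (length(cut) == 1) {
    out <- rep(unname(cols[1]), length(rejoin))
    names(out) <- rejoin
    return(out)
  }
  cut <- str_sort(cut)
  cols <- vapply(cut, function(a) colvec[[a]], character(1))
  if (length(rejoin) == 1) {
    out <- unname(cols[1]); names(out) <- rejoin
    return(out)
  }
  e1 <- adj_first_ext(cut[1])
  in_r1 <- e1 %in% adj_ends(rejoin[1])
  out <- if (in_r1) c(cols[1], cols[2]) else c(cols[2], cols[1])
  out <- unname(out); names(out) <- rejoin
  out
}

# core application on an adjacency string set and plain color vector
apply_move_adj <- function(adjset, colvec, m) {
  missing <- setdiff(m$cut, adjset)
  if (length(missing))
    grcs_abort(sprintf("cut adjacency not present in genome: %s",
                       paste(missing, collapse = ", ")),
               "grcs_invalid_move")
  newadj <- c(setdiff(adjset, m$cut), m$rejoin)
  if (is.null(colvec)) return(list(adj = newadj, col = NULL))
  assigned <- if (is.null(m$colors)) {
    default_color_assignment(m$cut, m$rejoin, colvec)
  } else m$colors
  colvec <- colvec[setdiff(names(colvec), m$cut)]
  colvec[names(assigned)] <- assigned
  list(adj = newadj, col = colvec)
}

#' Apply a DCJ move to a genome and its color map
#'
#' Untouched adjacencies keep their colors; the colors of the cut edges are
#' routed onto the resulting adjacencies by the move's color assignment (a
#' single-adjacency cut duplicates its color onto both new telomeric
#' adjacencies).
#'
#' @param g a `genome`.
#' @param col a `color_map` for `g`, or `NULL`.
#' @param m a `dcj_move`.
#' @return list with elements `genome` and `colors`.
#' @export
apply_move <- function(g, col, m) {
  adjset <- genome_to_adjacencies(g)
  res <- apply_move_adj(adjset, if (is.null(col)) NULL else unclass(col), m)
  g2 <- adjacencies_to_genome(res$adj, name = g$name)
  col2 <- if (is.null(res$col)) NULL else color_map(res$col, g2)
  list(genome = g2, colors = col2)
}

#' Binary positional weight of a DCJ move
#'
#' Weight 0 (a "likely" move) when the move cuts a single adjacency or when
#' both cut adjacencies have the same color; weight 1 (a "rare" move)
#' otherwise.
#'
#' @param m a `dcj_move`.
#' @param col a `color_map` covering the cut adjacencies.
#' @return 0 or 1.
#' @export
move_weight <- function(m, col) {
  cols <- unclass(col)[m$cut]
  if (anyNA(cols))
    grcs_abort(sprintf("uncolored cut adjacency: %s",
                       paste(m$cut[is.na(cols)], collapse = ", ")),
               "grcs_color_error")
  if (length(m$cut) == 1L || cols[1] == cols[2]) 0L else 1L
}

# ---------------------------------------------------------------------------
# Enumeration of sorting moves, component by component:
#  - cutting two A-edges of one component with the splitting rejoin extracts
#    a cycle (for an AA-path the pair of telomeric edges fuses the whole
#    path into a cycle);
#  - a single cut of any A-edge of a BB-path splits it into two odd paths
#    (the split in the genome with fewer vertices in the path);
#  - cutting one A-edge of an AA-path and one of a BB-path mixes them into
#    two odd paths; both reglueings sort.
# ---------------------------------------------------------------------------

# splitting rejoin for A-edges at traversal positions i < x of one component
split_rejoin <- function(ae, i, x) {
  new_cycle <- adjacency(ae$second[i], ae$first[x])
  if (ae$first[i] == TELOMERE && ae$second[x] == TELOMERE) {
    c(new_cycle)
  } else {
    c(new_cycle, adjacency(ae$first[i], ae$second[x]))
  }
}

moves_from_graph <- function(graph) {
  moves <- list()
  comps <- graph$components
  for (cp in comps) {
    ae <- cp$a_edges
    n <- cp$n_a
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (x in seq(i + 1, n)) {
          moves <- c(moves, list(dcj_move(
            cut = c(ae$adjacency[i], ae$adjacency[x]),
            rejoin = split_rejoin(ae, i, x))))
        }
      }
    }
    if (cp$kind == "BB_path") {
      for (i in seq_len(n)) {
        moves <- c(moves, list(dcj_move(
          cut = ae$adjacency[i],
          rejoin = c(adjacency(ae$first[i], TELOMERE),
                     adjacency(ae$second[i], TELOMERE)))))
      }
    }
  }
  aa <- Filter(function(cp) cp$kind == "AA_path", comps)
  bb <- Filter(function(cp) cp$kind == "BB_path", comps)
  for (p in aa) {
    for (q in bb) {
      for (i in seq_len(p$n_a)) {
        for (j in seq_len(q$n_a)) {
          a <- p$a_edges$first[i];  b <- p$a_edges$second[i]
          c_ <- q$a_edges$first[j]; d <- q$a_edges$second[j]
          cut <- c(p$a_edges$adjacency[i], q$a_edges$adjacency[j])
          moves <- c(moves, list(
            dcj_move(cut, c(adjacency(a, c_), adjacency(b, d))),
            dcj_move(cut, c(adjacency(a, d), adjacency(b, c_)))))
        }
      }
    }
  }
  moves
}

#' Enumerate all sorting DCJ moves
#'
#' Returns exactly the DCJ moves whose application reduces the DCJ distance
#' to `b` by one, derived structurally from the components of the adjacency
#' graph.  Moves carry no explicit color assignment (both routings of a
#' rare move share the same genome outcome).
#'
#' @param a,b `genome` objects with equal block content.
#' @param col optional `color_map` for `a` (colors are attached to the
#'   underlying graph but do not change the move set).
#' @return list of `dcj_move` objects; empty when `a` equals `b`.
#' @export
enumerate_sorting_moves <- function(a, b, col = NULL) {
  moves_from_graph(build_graph(a, b, col))
}
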