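# ---------------------------------------------------------------------------
# The colored adjacency graph G(A, B, col).
#
# Vertices are block extremities and (per-occurrence) telomeres of both
# genomes; adjacency edges join the two ends of each adjacency, cross edges
# join equal-labelled extremities across genomes.  Both edge families are
# matchings, so every connected component is a cycle or a path.  Components
# are stored as ordered traversals; A-side adjacency edges carry the colors
# of the color map.
# ---------------------------------------------------------------------------

# locale-independent deterministic string sort
str_sort <- function(x) sort(x, method = "radix")

other_adj_end <- function(ends, entry) if (ends[1] == entry) ends[2] else ends[1]

# core component builder on adjacency string sets; colors may be NULL
ag_core <- function(adjA, adjB, colors = NULL) {
  adjA <- str_sort(adjA)
  adjB <- str_sort(adjB)
  endsA <- lapply(adjA, adj_ends)
  endsB <- lapply(adjB, adj_ends)
  ext2adj <- function(adjs, ends) {
    m <- new.env(parent = emptyenv())
    for (i in seq_along(adjs)) {
      for (e in ends[[i]]) if (e != TELOMERE) assign(e, adjs[i], envir = m)
    }
    m
  }
  mapA <- ext2adj(adjA, endsA)
  mapB <- ext2adj(adjB, endsB)
  endsOf <- new.env(parent = emptyenv())
  for (i in seq_along(adjA)) assign(paste0("A:", adjA[i]), endsA[[i]], envir = endsOf)
  for (i in seq_along(adjB)) assign(paste0("B:", adjB[i]), endsB[[i]], envir = endsOf)

  visited <- new.env(parent = emptyenv())
  comps <- list()

  edge_color <- function(adj) {
    if (is.null(colors)) NA_character_ else unname(colors[[adj]])
  }

  walk_path <- function(start_side, start_adj) {
    side <- start_side; adj <- start_adj; entry <- TELOMERE
    cross <- character(0)
    a_adj <- character(0); a_first <- character(0); a_second <- character(0)
    repeat {
      ends <- get(paste0(side, ":", adj), envir = endsOf)
      exit <- other_adj_end(ends, entry)
      assign(paste0(side, ":", adj), TRUE, envir = visited)
      if (side == "A") {
        a_adj <- c(a_adj, adj); a_first <- c(a_first, entry); a_second <- c(a_second, exit)
      }
      if (exit == TELOMERE) {
        kind <- if (length(cross) %% 2 == 1) "odd_path"
                else if (start_side == "A") "AA_path" else "BB_path"
        return(list(kind = kind, cross = cross,
                    a_adj = a_adj, a_first = a_first, a_second = a_second))
      }
      cross <- c(cross, exit)
      side <- if (side == "A") "B" else "A"
      adj <- get(exit, envir = if (side == "A") mapA else mapB)
      entry <- exit
    }
  }

  walk_cycle <- function(start_adj) {
    ends <- get(paste0("A:", start_adj), envir = endsOf)
    # leave via the smaller-labelled extremity so the first cross edge
    # visited is the smaller of the two neighbors
    exit0 <- ends[which.min(ext_key(ends))]
    entry <- other_adj_end(ends, exit0)
    side <- "A"; adj <- start_adj
    cross <- character(0)
    a_adj <- character(0); a_first <- character(0); a_second <- character(0)
    repeat {
      ends <- get(paste0(side, ":", adj), envir = endsOf)
      exit <- other_adj_end(ends, entry)
      assign(paste0(side, ":", adj), TRUE, envir = visited)
      if (side == "A") {
        a_adj <- c(a_adj, adj); a_first <- c(a_first, entry); a_second <- c(a_second, exit)
      }
      cross <- c(cross, exit)
      side <- if (side == "A") "B" else "A"
      adj <- get(exit, envir = if (side == "A") mapA else mapB)
      entry <- exit
      if (side == "A" && adj == start_adj) break
    }
    list(kind = "cycle", cross = cross,
         a_adj = a_adj, a_first = a_first, a_second = a_second)
  }

  finish <- function(w, id) {
    n_a <- length(w$a_adj)
    D <- if (w$kind == "BB_path") n_a else n_a - 1L
    structure(list(id = id, kind = w$kind, cross = w$cross,
                   length = length(w$cross), n_a = n_a, D = as.integer(D),
                   a_edges = data.frame(adjacency = w$a_adj,
                                        first = w$a_first,
                                        second = w$a_second,
                                        color = vapply(w$a_adj, edge_color,
                                                       character(1)),
                                        row.names = NULL,
                                        stringsAsFactors = FALSE)),
              class = "dcj_component")
  }

  telA <- adjA[vapply(adjA, adj_is_telomeric, logical(1))]
  telB <- adjB[vapply(adjB, adj_is_telomeric, logical(1))]
  for (adj in telA) {
    if (exists(paste0("A:", adj), envir = visited)) next
    comps <- c(comps, list(walk_path("A", adj)))
  }
  for (adj in telB) {
    if (exists(paste0("B:", adj), envir = visited)) next
    comps <- c(comps, list(walk_path("B", adj)))
  }
  for (adj in adjA) {
    if (exists(paste0("A:", adj), envir = visited)) next
    comps <- c(comps, list(walk_cycle(adj)))
  }
  comps <- Map(finish, comps, seq_along(comps))

  kinds <- vapply(comps, function(cp) cp$kind, character(1))
  extsA <- unlist(endsA)
  N <- as.integer(sum(extsA != TELOMERE) / 2)
  structure(list(components = comps, N = N,
                 C = as.integer(sum(kinds == "cycle")),
                 I = as.integer(sum(kinds == "odd_path"))),
            class = "adjacency_graph")
}

#' Build the colored adjacency graph of two genomes
#'
#' @param a,b `genome` objects with equal block content.
#' @param col a `color_map` over the adjacencies of `a`, or `NULL` for an
#'   uncolored graph.
#' @return an `adjacency_graph`: a list with `components` (each of class
#'   `dcj_component` with fields `kind`, `cross`, `length`, `n_a`, `D` and
#'   the ordered A-side edge table `a_edges`), the block count `N`, the
#'   cycle count `C` and the odd-path count `I`.
#' @export
build_graph <- function(a, b, col = NULL) {
  validate_equal_content(a, b)
  adjA <- genome_to_adjacencies(a)
  if (!is.null(col)) {
    if (!setequal(names(col), adjA))
      grcs_abort("color map does not match the adjacencies of genome A",
                 "grcs_color_error")
  }
  ag_core(adjA, genome_to_adjacencies(b), col)
}

#' Classify a connected component of the adjacency graph
#'
#' @param comp a `dcj_component`.
#' @return one of `"cycle"`, `"odd_path"`, `"AA_path"`, `"BB_path"`.
#' @export
classify_component <- function(comp) comp$kind

#' @export
print.dcj_component <- function(x, ...) {
  cat(sprintf("component %s: %s, length %d, A-edges: %s\n",
              x$id, x$kind, x$length,
              paste(x$a_edges$adjacency, collapse = " ")))
  invisible(x)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("adjacency graph: N=%d, C=%d, I=%d, %d component(s)\n",
              x$N, x$C, x$I, length(x$components)))
  for (cp in x$components) print(cp)
  invisible(x)
}

#' DCJ distance between two genomes
#'
#' Computed as `N - (C + I/2)` where `N` is the number of blocks, `C` the
#' number of cycles and `I` the number of odd-length paths of the adjacency
#' graph.
#'
#' @param a,b `genome` objects with equal block content.
#' @return non-negative integer distance.
#' @export
dcj_distance <- function(a, b) {
  g <- build_graph(a, b)
  d <- g$N - (g$C + g$I / 2)
  stopifnot(d >= 0, d == round(d))
  as.integer(d)
}
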