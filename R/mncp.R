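# ---------------------------------------------------------------------------
# Minimum Noncrossing Colored Partition (MNCP).
#
# Given colors col(1..n), find a partition of [1,n] of minimum cardinality
# such that classes are monochromatic and no two classes cross
# (p < q < p' < q' with p,p' and q,q' in different classes).  A partition is
# noncrossing on a circle iff it is noncrossing on the line obtained by
# cutting the circle anywhere, so the same program serves cycle components
# (where the embedding is circular) and path components.
# ---------------------------------------------------------------------------

as_color_vector <- function(seq) {
  if (inherits(seq, "colored_sequence")) seq$colors else as.character(seq)
}

#' Colored sequence of a component's A-side edges
#'
#' Positions 1..n are the component's A-side adjacency edges in traversal
#' order (the circular embedding for cycles).
#'
#' @param comp a `dcj_component` built from a colored graph.
#' @return an object of class `colored_sequence` with fields `colors`,
#'   `circular` and the originating `component`.
#' @export
component_sequence <- function(comp) {
  if (comp$n_a < 1)
    grcs_abort("component has no A-side adjacency edges", "grcs_internal")
  colors <- comp$a_edges$color
  if (anyNA(colors))
    grcs_abort("component was built without a color map", "grcs_color_error")
  structure(list(colors = colors, circular = comp$kind == "cycle",
                 component = comp),
            class = "colored_sequence")
}

#' Minimum Noncrossing Colored Partition
#'
#' Dynamic program over intervals: `NCP(i,i) = 1` and
#' `NCP(i,j) = min( NCP(i,j-1)+1,  NCP(i,j-1) if col(i)=col(j),
#' min over i<k<j of NCP(i,k-1)+NCP(k,j) )`.  Ties are broken by taking the
#' first minimizer in that case order (new singleton; join ends; split at
#' the smallest k), which makes the returned partition deterministic.
#' Runs in O(n^3) time and O(n^2) space.
#'
#' @param seq a `colored_sequence` or a character vector of colors.
#' @return list with `k` (minimum cardinality), `classes` (list of sorted
#'   integer vectors, ordered by smallest member), `n` and `colors`.
#' @export
mncp <- function(seq) {
  colors <- as_color_vector(seq)
  n <- length(colors)
  stopifnot(n >= 1)
  if (n == 1)
    return(list(k = 1L, classes = list(1L), n = 1L, colors = colors))
  K <- matrix(0L, n, n)
  CH <- matrix(0L, n, n)   # 1 = new singleton, 2 = join i..j, -k = split at k
  diag(K) <- 1L
  for (len in 1:(n - 1)) {
    for (i in 1:(n - len)) {
      j <- i + len
      best <- K[i, j - 1] + 1L; ch <- 1L
      if (colors[i] == colors[j] && K[i, j - 1] < best) {
        best <- K[i, j - 1]; ch <- 2L
      }
      if (len >= 2) {
        for (k in (i + 1):(j - 1)) {
          v <- K[i, k - 1] + K[k, j]
          if (v < best) { best <- v; ch <- -k }
        }
      }
      K[i, j] <- best; CH[i, j] <- ch
    }
  }
  trace <- function(i, j) {
    if (i == j) return(list(i))
    ch <- CH[i, j]
    if (ch == 1L) {
      c(trace(i, j - 1), list(j))
    } else if (ch == 2L) {
      p <- trace(i, j - 1)
      w <- which(vapply(p, function(s) i %in% s, logical(1)))
      p[[w]] <- c(p[[w]], j)
      p
    } else {
      k <- -ch
      c(trace(i, k - 1), trace(k, j))
    }
  }
  classes <- lapply(trace(1, n), function(s) sort(as.integer(s)))
  classes <- classes[order(vapply(classes, min, integer(1)))]
  stopifnot(length(classes) == K[1, n])
  list(k = as.integer(K[1, n]), classes = classes, n = as.integer(n),
       colors = colors)
}

#' Check a partition for the noncrossing and colored conditions
#'
#' @param classes list of integer vectors partitioning `[1,n]`.
#' @param seq a `colored_sequence` or character vector of colors.
#' @return `TRUE` iff no two classes cross and every class is monochromatic.
#' @export
is_noncrossing_colored <- function(classes, seq) {
  colors <- as_color_vector(seq)
  n <- length(colors)
  all_members <- sort(unlist(classes))
  if (!identical(as.integer(all_members), seq_len(n)))
    grcs_abort("classes must partition [1,n]", "grcs_invalid_partition")
  mono <- all(vapply(classes, function(s) length(unique(colors[s])) == 1,
                     logical(1)))
  if (!mono) return(FALSE)
  k <- length(classes)
  if (k >= 2) {
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        u <- sort(c(classes[[a]], classes[[b]]))
        lab <- u %in% classes[[a]]
        if (length(rle(lab)$lengths) >= 4) return(FALSE)
      }
    }
  }
  TRUE
}

#' Brute-force minimum noncrossing colored partition
#'
#' Exhaustively enumerates noncrossing colored partitions by assigning
#' positions left to right (an incremental crossing check makes the search
#' tree a subtree of the full Bell-number recursion), returning the minimum
#' cardinality.  Testing oracle for [mncp()]; guarded to small n.
#'
#' @param seq a `colored_sequence` or character vector of colors.
#' @param max_n size guard (default 12).
#' @return minimum number of classes.
#' @export
brute_force_mncp <- function(seq, max_n = 12L) {
  colors <- as_color_vector(seq)
  n <- length(colors)
  if (n > max_n)
    grcs_abort(sprintf("brute_force_mncp is limited to n <= %d", max_n),
               "grcs_size_guard")
  best <- n  # all singletons is always feasible
  recurse <- function(j, classes, class_colors) {
    if (length(classes) >= best && j <= n) {
      # can only grow or stay; prune when already no better
      if (length(classes) >= best) return()
    }
    if (j > n) {
      if (length(classes) < best) best <<- length(classes)
      return()
    }
    # try joining each existing class of the same color
    for (ci in seq_along(classes)) {
      if (class_colors[ci] != colors[j]) next
      s <- classes[[ci]]
      crosses <- FALSE
      for (ti in seq_along(classes)) {
        if (ti == ci) next
        t <- classes[[ti]]
        # adding j to s crosses t iff some q in s has t-elements on both
        # sides within (min(t), j)
        for (q in s) {
          if (any(t < q) && any(t > q & t < j)) { crosses <- TRUE; break }
        }
        if (crosses) break
      }
      if (!crosses) {
        classes2 <- classes; classes2[[ci]] <- c(s, j)
        recurse(j + 1, classes2, class_colors)
      }
    }
    # or open a new class
    recurse(j + 1, c(classes, list(j)), c(class_colors, colors[j]))
  }
  recurse(2L, list(1L), colors[1])
  as.integer(best)
}

# ---------------------------------------------------------------------------
# Realizing a partition as DCJ splits.
#
# A partition of cardinality k is achieved with k-1 sorting DCJs: a
# noncrossing partition always has a class that is contiguous in the current
# embedding; one DCJ cuts a boundary edge of that class together with its
# neighbor from a different class and extracts the class as a cycle, the
# color assignment routing each surviving color into the sub-component that
# holds its class.
# ---------------------------------------------------------------------------

#' Convert a component and a noncrossing colored partition into DCJ splits
#'
#' @param comp a `dcj_component` built from a colored graph.
#' @param classes list of integer vectors: a noncrossing colored partition
#'   of the component's A-edge positions (as returned by [mncp()]).
#' @param check when `TRUE` (default) assert after every split that the
#'   remaining classes are still noncrossing in the embedding.
#' @return list of `dcj_move` objects of length `k - 1`, in application
#'   order; each move carries its explicit color assignment.
#' @export
partition_to_splits <- function(comp, classes, check = TRUE) {
  seq <- component_sequence(comp)
  if (!is_noncrossing_colored(classes, seq))
    grcs_abort("partition is not noncrossing colored for this component",
               "grcs_invalid_partition")
  m <- comp$n_a
  class_of <- integer(m)
  for (ci in seq_along(classes)) class_of[classes[[ci]]] <- ci
  W <- list(id = seq_len(m),
            adj = comp$a_edges$adjacency,
            first = comp$a_edges$first,
            second = comp$a_edges$second,
            color = comp$a_edges$color)
  circular <- comp$kind == "cycle"
  moves <- list()

  while (length(unique(class_of[W$id])) > 1) {
    mm <- length(W$id)
    labs <- class_of[W$id]
    # candidate contiguous classes, by first appearance in the embedding
    cand <- NULL
    for (ci in unique(labs)) {
      pos <- which(labs == ci)
      lin <- (max(pos) - min(pos) + 1L) == length(pos)
      wrap <- FALSE
      if (!lin && circular) {
        comp_pos <- setdiff(seq_len(mm), pos)
        wrap <- (max(comp_pos) - min(comp_pos) + 1L) == length(comp_pos) &&
          min(comp_pos) > 1L && max(comp_pos) < mm
      }
      if (!lin && !wrap) next
      if (wrap) {
        # rotate so the run becomes linear
        off <- max(setdiff(seq_len(mm), pos))  # last position of complement
        rot <- c(seq(off + 1L, mm), seq_len(off))
        Wr <- lapply(W, function(v) v[rot])
        posr <- which(class_of[Wr$id] == ci)
      } else {
        Wr <- W; posr <- pos
      }
      r1 <- min(posr); r2 <- max(posr)
      if (r2 == r1 - 1L + length(posr) && r2 - r1 + 1L == length(posr)) {
        # choose cut neighbors; skip degenerate telomere-telomere products
        if (r2 < length(Wr$id)) {
          if (!(Wr$first[r1] == TELOMERE && Wr$second[r2 + 1L] == TELOMERE)) {
            cand <- list(W = Wr, r1 = r1, r2 = r2, side = "after"); break
          }
        }
        if (r1 > 1L) {
          if (!(Wr$first[r1 - 1L] == TELOMERE && Wr$second[r2] == TELOMERE)) {
            cand <- list(W = Wr, r1 = r1, r2 = r2, side = "before"); break
          }
        }
      }
    }
    if (is.null(cand)) {
      # an even path reduced to its two telomeric A-edges in different
      # classes: the single remaining move is the telomere-absorbing fusion,
      # which closes the component into a trivial cycle
      if (!circular && mm == 2L && W$first[1] == TELOMERE &&
          W$second[2] == TELOMERE && labs[1] != labs[2]) {
        e_star <- adjacency(W$second[1], W$first[2])
        cols <- W$color[1]; names(cols) <- e_star
        moves <- c(moves, list(dcj_move(c(W$adj[1], W$adj[2]), e_star,
                                        colors = cols)))
        W <- lapply(W, function(v) v[integer(0)])
        break
      }
      grcs_abort("no extractable contiguous class found (internal error)",
                 "grcs_internal")
    }
    W <- cand$W; r1 <- cand$r1; r2 <- cand$r2
    if (cand$side == "after") {
      i <- r1; x <- r2 + 1L
      e_star <- adjacency(W$second[i], W$first[x])     # closes the run cycle
      e_rest <- adjacency(W$first[i], W$second[x])
      cols <- c(W$color[i], W$color[x]); names(cols) <- c(e_star, e_rest)
      moves <- c(moves, list(dcj_move(c(W$adj[i], W$adj[x]),
                                      c(e_star, e_rest), colors = cols)))
      keep <- setdiff(seq_along(W$id), r1:r2)
      W$adj[x] <- e_rest; W$first[x] <- W$first[i]
      W <- lapply(W, function(v) v[keep])
    } else {
      w <- r1 - 1L; x <- r2
      e_star <- adjacency(W$second[w], W$first[x])
      e_rest <- adjacency(W$first[w], W$second[x])
      cols <- c(W$color[x], W$color[w]); names(cols) <- c(e_star, e_rest)
      moves <- c(moves, list(dcj_move(c(W$adj[w], W$adj[x]),
                                      c(e_star, e_rest), colors = cols)))
      keep <- setdiff(seq_along(W$id), r1:r2)
      W$adj[w] <- e_rest; W$second[w] <- W$second[x]
      W <- lapply(W, function(v) v[keep])
    }
    if (check) {
      rem <- class_of[W$id]
      # remaining classes, re-indexed on the surviving embedding, must
      # still be noncrossing (the colored condition is inherited)
      rem_classes <- split(seq_along(rem), rem)
      if (!is_noncrossing_colored(unname(rem_classes), W$color))
        grcs_abort("intermediate state has crossing adjacency edges",
                   "grcs_internal")
    }
  }
  if (length(moves) != length(classes) - 1L)
    grcs_abort("split realization did not use exactly k-1 moves",
               "grcs_internal")
  moves
}
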