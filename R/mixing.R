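# ---------------------------------------------------------------------------
# Mixing of even-length paths.
#
# The only sorting DCJ acting on two components takes one A-edge of an
# AA-path and one A-edge of a BB-path and produces two odd paths.  Whether
# mixing a pair gains likely moves is decided by comparing the MNCP on two
# cycles c1/c2 built from the pair (the two relative orientations of the
# paths) against sorting the paths separately; which pairs to mix is a
# maximum-weight matching over the AA x BB bipartite graph with "stay
# unmixed" encoded as a twin edge per path.
# ---------------------------------------------------------------------------

#' Number of likely moves when sorting a component on its own
#'
#' A component contributing D moves to a parsimonious scenario and with
#' minimum noncrossing colored partition cardinality k needs k - 1 rare
#' moves; the remaining D - (k - 1) are likely.
#'
#' @param comp a `dcj_component` built from a colored graph.
#' @return non-negative integer count of likely moves.
#' @export
likely_count <- function(comp) {
  k <- mncp(component_sequence(comp))$k
  as.integer(comp$D - (k - 1L))
}

#' Build the two mixed cycles of an AA-path / BB-path pair
#'
#' With `p` the AA-path with A-edges `e_1..e_k` (telomeres t1, t2) and `q`
#' the BB-path with A-edges `f_1..f_l` (telomeres t3, t4), cycle `c1` joins
#' t1-t3 and t2-t4, cycle `c2` joins t1-t4 and t2-t3; the two cycles carry
#' all A-edges of both paths and differ by the relative orientation of `q`.
#'
#' @param p a `dcj_component` of kind `AA_path`.
#' @param q a `dcj_component` of kind `BB_path`.
#' @return object of class `mixed_cycles` with circular color sequences
#'   `c1_colors`, `c2_colors`, the matching A-edge orders `c1_order`,
#'   `c2_order` (labels `e1..ek`, `f1..fl`), and the source pair.
#' @export
make_cycles <- function(p, q) {
  if (!identical(p$kind, "AA_path") || !identical(q$kind, "BB_path"))
    grcs_abort("make_cycles expects an AA-path then a BB-path",
               "grcs_kind_mismatch")
  e <- p$a_edges$color; f <- q$a_edges$color
  k <- length(e); l <- length(f)
  structure(list(
    c1_colors = c(e, rev(f)),
    c2_colors = c(e, f),
    c1_order = c(paste0("e", seq_len(k)), paste0("f", rev(seq_len(l)))),
    c2_order = c(paste0("e", seq_len(k)), paste0("f", seq_len(l))),
    p = p, q = q, n_a = k + l),
    class = "mixed_cycles")
}

# descending / ascending sequences that are empty when the range is empty
rseq <- function(a, b) if (a < b) integer(0) else a:b
fseq <- function(a, b) if (a > b) integer(0) else a:b

#' Maximum number of likely moves for a pair of even paths
#'
#' Computed from three MNCP calls: on the two mixed cycles `c1`/`c2` and on
#' the unmixed pair.  With `D = m_p + m_q - 1` the total number of moves the
#' mixed pair contributes, returns
#' `max(D - (k(c1)-1), D - (k(c2)-1), likely(p) + likely(q))`.
#'
#' @param p a `dcj_component` of kind `AA_path`.
#' @param q a `dcj_component` of kind `BB_path`.
#' @return non-negative integer number of likely moves.
#' @export
max_mix <- function(p, q) {
  mc <- make_cycles(p, q)
  D <- p$D + q$D  # = m_p + m_q - 1
  k1 <- mncp(mc$c1_colors)$k
  k2 <- mncp(mc$c2_colors)$k
  as.integer(max(D - (k1 - 1L), D - (k2 - 1L),
                 likely_count(p) + likely_count(q)))
}

# the four ways a DCJ on e_i and f_j redistributes the A-edges of the pair
# onto two odd paths (two reglueings x two color routings)
mix_case_sequences <- function(e, f, i, j, case) {
  k <- length(e); l <- length(f)
  switch(case,
    list(p1 = c(e[fseq(1, i)],     f[rseq(j - 1, 1)]),
         p2 = c(e[rseq(k, i + 1)], f[fseq(j, l)])),
    list(p1 = c(e[fseq(1, i - 1)], f[rseq(j, 1)]),
         p2 = c(e[rseq(k, i)],     f[fseq(j + 1, l)])),
    list(p1 = c(e[fseq(1, i)],     f[fseq(j + 1, l)]),
         p2 = c(e[rseq(k, i + 1)], f[rseq(j, 1)])),
    list(p1 = c(e[fseq(1, i - 1)], f[fseq(j, l)]),
         p2 = c(e[rseq(k, i)],     f[rseq(j - 1, 1)])))
}

#' Exhaustive maximum likely count over all mixings of a pair
#'
#' Enumerates every mixing DCJ (each A-edge pair `(e_i, f_j)`, both
#' reglueings, both color routings), scores the two resulting odd paths by
#' MNCP, and also considers not mixing at all.  Oracle counterpart of
#' [max_mix()].
#'
#' @param p a `dcj_component` of kind `AA_path`.
#' @param q a `dcj_component` of kind `BB_path`.
#' @param max_edges size guard on `m_p + m_q` (default 12).
#' @return non-negative integer number of likely moves.
#' @export
exhaustive_max_mix <- function(p, q, max_edges = 12L) {
  if (!identical(p$kind, "AA_path") || !identical(q$kind, "BB_path"))
    grcs_abort("exhaustive_max_mix expects an AA-path then a BB-path",
               "grcs_kind_mismatch")
  e <- p$a_edges$color; f <- q$a_edges$color
  if (length(e) + length(f) > max_edges)
    grcs_abort("exhaustive_max_mix is limited to small path pairs",
               "grcs_size_guard")
  D <- p$D + q$D
  best <- likely_count(p) + likely_count(q)
  for (i in seq_along(e)) {
    for (j in seq_along(f)) {
      w <- as.integer(e[i] != f[j])
      for (case in 1:4) {
        ps <- mix_case_sequences(e, f, i, j, case)
        rare <- w + (mncp(ps$p1)$k - 1L) + (mncp(ps$p2)$k - 1L)
        best <- max(best, D - rare)
      }
    }
  }
  as.integer(best)
}

#' Build the bipartite mixing graph over even-length paths
#'
#' Left vertices are the AA-paths, right vertices the BB-paths; each cross
#' edge `(p, q)` is weighted by [max_mix()] and each vertex has a twin edge
#' weighted by its own likely-move count (staying unmixed).
#'
#' @param components list of `dcj_component`s (non-even components are
#'   ignored), or an `adjacency_graph`.
#' @return object of class `mix_graph`.
#' @export
build_mix_graph <- function(components) {
  if (inherits(components, "adjacency_graph")) components <- components$components
  aa <- Filter(function(cp) cp$kind == "AA_path", components)
  bb <- Filter(function(cp) cp$kind == "BB_path", components)
  aa_ids <- vapply(aa, function(cp) paste0("AA", cp$id), character(1))
  bb_ids <- vapply(bb, function(cp) paste0("BB", cp$id), character(1))
  aa_likely <- vapply(aa, likely_count, integer(1))
  bb_likely <- vapply(bb, likely_count, integer(1))
  names(aa_likely) <- aa_ids; names(bb_likely) <- bb_ids
  W <- matrix(0L, length(aa), length(bb), dimnames = list(aa_ids, bb_ids))
  for (i in seq_along(aa)) {
    for (j in seq_along(bb)) W[i, j] <- max_mix(aa[[i]], bb[[j]])
  }
  structure(list(aa = aa, bb = bb, aa_ids = aa_ids, bb_ids = bb_ids,
                 weights = W, aa_likely = aa_likely, bb_likely = bb_likely),
            class = "mix_graph")
}

#' @export
print.mix_graph <- function(x, ...) {
  cat(sprintf("mixing graph: %d AA-path(s), %d BB-path(s)\n",
              length(x$aa), length(x$bb)))
  invisible(x)
}

#' Decide which even-path pairs to mix
#'
#' Finds a maximum-weight matching of the mixing graph in which every even
#' path is matched either to a partner or to its twin (unmixed).  Since
#' mixing `(p, q)` beats leaving both unmixed exactly when
#' `gain = max_mix(p,q) - likely(p) - likely(q) > 0`, this reduces to a
#' maximum-weight bipartite matching on the positive gains; ties break
#' toward not mixing.
#'
#' @param mg a `mix_graph`.
#' @return list with `pairs` (data frame of matched `p`/`q` component ids
#'   and their gain) and `total`, the maximum total number of likely moves
#'   spent on even-path components.
#' @export
optimal_mixing <- function(mg) {
  base <- sum(mg$aa_likely) + sum(mg$bb_likely)
  na <- length(mg$aa); nb <- length(mg$bb)
  empty <- data.frame(p = integer(0), q = integer(0), gain = integer(0))
  if (na == 0 || nb == 0)
    return(list(pairs = empty, total = as.integer(base)))
  gains <- mg$weights - outer(mg$aa_likely, mg$bb_likely, `+`)
  idx <- which(gains > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(pairs = empty, total = as.integer(base)))
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, na), rep(TRUE, nb))
  edges <- as.vector(t(cbind(idx[, 1], na + idx[, 2])))
  g <- igraph::add_edges(g, edges)
  m <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                   weights = gains[idx])
  mate <- m$matching
  pairs <- empty
  for (i in seq_len(na)) {
    if (!is.na(mate[i]) && mate[i] > 0) {
      j <- mate[i] - na
      pairs <- rbind(pairs, data.frame(p = mg$aa[[i]]$id, q = mg$bb[[j]]$id,
                                       gain = gains[i, j]))
    }
  }
  list(pairs = pairs, total = as.integer(base + sum(pairs$gain)))
}
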