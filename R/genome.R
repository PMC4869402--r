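#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Block extremities, adjacencies and genomes.
#
# A syntenic block b has a tail extremity "bt" and a head extremity "bh".
# The telomere marker is "$".  An adjacency is an unordered pair of ends,
# at most one of which is the telomere marker; it is stored as a canonical
# string such as "1h-2t" or "5t-$" (telomere second, extremities ordered by
# block id then head before tail).
# ---------------------------------------------------------------------------

TELOMERE <- "$"

grcs_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "grcs_error")))
}

#' Render a block extremity token
#'
#' @param block positive integer block identifier.
#' @param end `"h"` (head) or `"t"` (tail).
#' @return character token such as `"5h"`.
#' @export
extremity <- function(block, end) {
  stopifnot(block >= 1, end %in% c("h", "t"))
  paste0(block, end)
}

# sort key for an extremity token; telomeres sort last
ext_key <- function(x) {
  k <- numeric(length(x))
  tel <- x == TELOMERE
  k[tel] <- Inf
  if (any(!tel)) {
    b <- as.integer(sub("[ht]$", "", x[!tel]))
    e <- substring(x[!tel], nchar(x[!tel]))
    k[!tel] <- 2 * b + (e == "t")
  }
  k
}

ext_block <- function(x) as.integer(sub("[ht]$", "", x))

#' Build the canonical string form of an adjacency
#'
#' Orders the pair so that a telomere marker comes second and extremities
#' are sorted by block identifier, head before tail.
#'
#' @param u,v extremity tokens or the telomere marker `"$"`.
#' @return canonical adjacency string, e.g. `"1h-2t"` or `"5t-$"`.
#' @export
adjacency <- function(u, v) {
  if (u == TELOMERE && v == TELOMERE)
    grcs_abort("the pair {telomere, telomere} is not an adjacency",
               "grcs_invalid_adjacency")
  if (u != TELOMERE && u == v)
    grcs_abort(sprintf("degenerate adjacency {%s,%s}", u, v),
               "grcs_invalid_adjacency")
  if (ext_key(u) <= ext_key(v)) paste0(u, "-", v) else paste0(v, "-", u)
}

adj_ends <- function(adj) strsplit(adj, "-", fixed = TRUE)[[1]]

adj_is_telomeric <- function(adj) endsWith(adj, paste0("-", TELOMERE))

# vectorised canonicalization of many (u, v) pairs
adj_make_vec <- function(u, v) {
  swap <- ext_key(u) > ext_key(v)
  a <- ifelse(swap, v, u)
  b <- ifelse(swap, u, v)
  paste0(a, "-", b)
}

# ---------------------------------------------------------------------------
# Genome construction and validation
# ---------------------------------------------------------------------------

new_chromosome <- function(blocks, circular) {
  blocks <- as.integer(blocks)
  if (length(blocks) == 0)
    grcs_abort("empty chromosome", "grcs_empty_chromosome")
  if (any(blocks == 0))
    grcs_abort("block identifier 0 is not allowed", "grcs_malformed_token")
  if (anyDuplicated(abs(blocks)))
    grcs_abort("duplicate block within a chromosome", "grcs_duplicate_block")
  list(blocks = blocks, circular = isTRUE(circular))
}

#' Construct a genome from chromosomes
#'
#' @param chromosomes list of chromosomes; each a list with fields `blocks`
#'   (signed integer vector) and `circular` (logical), as returned by the
#'   parser.  A bare integer vector is taken as a linear chromosome.
#' @param name optional genome name.
#' @return an object of class `genome`.
#' @export
genome <- function(chromosomes, name = NULL) {
  chromosomes <- lapply(chromosomes, function(ch) {
    if (is.numeric(ch)) ch <- list(blocks = ch, circular = FALSE)
    new_chromosome(ch$blocks, ch$circular)
  })
  ids <- unlist(lapply(chromosomes, function(ch) abs(ch$blocks)))
  if (anyDuplicated(ids))
    grcs_abort(sprintf("duplicate block(s) across chromosomes: %s",
                       paste(sort(unique(ids[duplicated(ids)])), collapse = ", ")),
               "grcs_duplicate_block")
  structure(list(name = name, chromosomes = chromosomes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome %s: %d block(s), %d chromosome(s)\n",
              if (is.null(x$name)) "<unnamed>" else x$name,
              n_blocks(x), length(x$chromosomes)))
  for (ch in x$chromosomes) {
    cat(" ", paste(ch$blocks, collapse = " "),
        if (ch$circular) "@" else "$", "\n")
  }
  invisible(x)
}

#' Number of blocks in a genome
#' @param g a `genome`.
#' @return integer block count N.
#' @export
n_blocks <- function(g) {
  sum(vapply(g$chromosomes, function(ch) length(ch$blocks), integer(1)))
}

#' Block identifier set of a genome
#' @param g a `genome`.
#' @return sorted integer vector of (unsigned) block ids.
#' @export
block_ids <- function(g) {
  sort(unlist(lapply(g$chromosomes, function(ch) abs(ch$blocks))))
}

n_linear <- function(g) {
  sum(!vapply(g$chromosomes, function(ch) ch$circular, logical(1)))
}

# left/right extremity of a signed block read left to right:
# +b is entered at its tail and left at its head.
block_left_ext  <- function(b) paste0(abs(b), ifelse(b > 0, "t", "h"))
block_right_ext <- function(b) paste0(abs(b), ifelse(b > 0, "h", "t"))

#' Convert a genome to its adjacency set
#'
#' A linear chromosome of k blocks yields k+1 adjacencies (two of them
#' telomeric); a circular chromosome yields k adjacencies.
#'
#' @param g a `genome`.
#' @return character vector of canonical adjacency strings (unordered set).
#' @export
genome_to_adjacencies <- function(g) {
  out <- character(0)
  for (ch in g$chromosomes) {
    b <- ch$blocks
    k <- length(b)
    if (ch$circular) {
      u <- block_right_ext(b)
      v <- block_left_ext(b[c(seq_len(k)[-1], 1L)])
      out <- c(out, adj_make_vec(u, v))
    } else {
      u <- c(TELOMERE, block_right_ext(b))
      v <- c(block_left_ext(b), TELOMERE)
      out <- c(out, adj_make_vec(u, v))
    }
  }
  out
}

#' Reconstruct a genome from an adjacency set
#'
#' Inverse of [genome_to_adjacencies()].  Chromosomes are put into canonical
#' form: a linear chromosome is oriented so that its first block is positive
#' if possible, otherwise so that the smaller absolute block id comes first;
#' a circular chromosome is rotated to start at its smallest absolute block
#' id, oriented so that this block is positive.
#'
#' @param adjs character vector of canonical adjacency strings forming a
#'   perfect matching over all extremities (plus telomere markers).
#' @param name optional genome name.
#' @return a `genome`.
#' @export
adjacencies_to_genome <- function(adjs, name = NULL) {
  ends <- strsplit(adjs, "-", fixed = TRUE)
  exts <- unlist(ends)
  exts <- exts[exts != TELOMERE]
  if (anyDuplicated(exts))
    grcs_abort(sprintf("extremity used twice: %s",
                       paste(unique(exts[duplicated(exts)]), collapse = ", ")),
               "grcs_structural_error")
  blocks <- sort(unique(ext_block(exts)))
  need <- c(paste0(blocks, "h"), paste0(blocks, "t"))
  missing <- setdiff(need, exts)
  if (length(missing))
    grcs_abort(sprintf("missing extremity: %s", paste(missing, collapse = ", ")),
               "grcs_structural_error")

  # partner map: extremity -> the other end of its adjacency
  partner <- new.env(parent = emptyenv())
  for (e in ends) {
    if (e[1] != TELOMERE) assign(e[1], e[2], envir = partner)
    if (e[2] != TELOMERE) assign(e[2], e[1], envir = partner)
  }
  other_end <- function(x) {
    b <- sub("[ht]$", "", x)
    if (endsWith(x, "h")) paste0(b, "t") else paste0(b, "h")
  }
  used <- new.env(parent = emptyenv())
  chroms <- list()

  walk <- function(start_ext) {
    # start_ext is the left extremity of the first block of a chromosome
    seq_blocks <- integer(0)
    cur <- start_ext
    repeat {
      b <- ext_block(cur)
      signed <- if (endsWith(cur, "t")) b else -b
      seq_blocks <- c(seq_blocks, signed)
      assign(cur, TRUE, envir = used)
      out <- other_end(cur)
      assign(out, TRUE, envir = used)
      nxt <- get(out, envir = partner)
      if (nxt == TELOMERE) return(list(blocks = seq_blocks, closed = FALSE))
      if (nxt == start_ext) return(list(blocks = seq_blocks, closed = TRUE))
      cur <- nxt
    }
  }

  # linear chromosomes start at the non-telomere end of telomeric adjacencies
  tel_starts <- unlist(lapply(ends, function(e) {
    if (any(e == TELOMERE)) e[e != TELOMERE] else character(0)
  }))
  tel_starts <- tel_starts[order(ext_key(tel_starts))]
  for (s in tel_starts) {
    if (exists(s, envir = used)) next
    res <- walk(s)
    chroms <- c(chroms, list(list(blocks = canon_linear(res$blocks),
                                  circular = FALSE)))
  }
  # remaining extremities belong to circular chromosomes
  for (s in exts[order(ext_key(exts))]) {
    if (exists(s, envir = used)) next
    res <- walk(s)
    chroms <- c(chroms, list(list(blocks = canon_circular(res$blocks),
                                  circular = TRUE)))
  }
  g <- genome(chroms, name = name)
  got <- sort(genome_to_adjacencies(g))
  if (!identical(got, sort(unname(adjs))))
    grcs_abort("adjacency set does not describe a genome", "grcs_structural_error")
  g
}

canon_linear <- function(blocks) {
  rev_blocks <- -rev(blocks)
  if (blocks[1] > 0 && rev_blocks[1] > 0) {
    if (abs(blocks[1]) <= abs(rev_blocks[1])) blocks else rev_blocks
  } else if (blocks[1] > 0) {
    blocks
  } else if (rev_blocks[1] > 0) {
    rev_blocks
  } else {
    if (abs(blocks[1]) <= abs(rev_blocks[1])) blocks else rev_blocks
  }
}

canon_circular <- function(blocks) {
  i <- which.min(abs(blocks))
  k <- length(blocks)
  rot <- blocks[c(seq(i, k), if (i > 1) seq(1, i - 1))]
  if (rot[1] < 0) rot <- canon_circular_flip(rot)
  rot
}

canon_circular_flip <- function(rot) {
  # reverse orientation, then rotate so the smallest block leads again
  flipped <- -rev(rot)
  i <- which.min(abs(flipped))
  k <- length(flipped)
  flipped[c(seq(i, k), if (i > 1) seq(1, i - 1))]
}

#' Check that two genomes have identical block content
#'
#' @param a,b `genome` objects.
#' @return invisibly `TRUE`; raises an error naming the symmetric difference
#'   of the block sets when content differs.
#' @export
validate_equal_content <- function(a, b) {
  ia <- block_ids(a); ib <- block_ids(b)
  if (!identical(ia, ib)) {
    d <- sort(union(setdiff(ia, ib), setdiff(ib, ia)))
    grcs_abort(sprintf("genomes do not have equal content; differing blocks: {%s}",
                       paste(d, collapse = ",")),
               "grcs_content_mismatch")
  }
  invisible(TRUE)
}

genomes_equal <- function(a, b) {
  setequal(genome_to_adjacencies(a), genome_to_adjacencies(b))
}

# ---------------------------------------------------------------------------
# Genome file dialect
#
#   > name          header starts a genome
#   5 -1 -2 6 $     linear chromosome ("$" terminator)
#   9 10 @          circular chromosome ("@" terminator)
#   # comment
# ---------------------------------------------------------------------------

#' Parse genomes from text in the block-list dialect
#'
#' @param text character scalar (file content) or character vector of lines.
#' @return named list of `genome` objects.
#' @export
parse_genomes <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  flush <- function() {
    if (is.null(cur_name)) return()
    if (length(cur_chroms) == 0)
      grcs_abort(sprintf("genome '%s' has no chromosomes", cur_name),
                 "grcs_empty_chromosome")
    genomes[[cur_name]] <<- genome(cur_chroms, name = cur_name)
  }
  for (ln in lines) {
    s <- trimws(ln)
    if (s == "" || startsWith(s, "#")) next
    if (startsWith(s, ">")) {
      flush()
      cur_name <- trimws(substring(s, 2))
      if (cur_name == "") cur_name <- sprintf("genome%d", length(genomes) + 1L)
      cur_chroms <- list()
      next
    }
    if (is.null(cur_name))
      grcs_abort("chromosome line before any '>' header", "grcs_malformed_token")
    toks <- strsplit(s, "[[:space:]]+")[[1]]
    term <- toks[length(toks)]
    if (!term %in% c("$", "@"))
      grcs_abort(sprintf("chromosome line missing '$' or '@' terminator: '%s'", s),
                 "grcs_missing_terminator")
    body <- toks[-length(toks)]
    if (length(body) == 0)
      grcs_abort("empty chromosome", "grcs_empty_chromosome")
    if (!all(grepl("^-?[0-9]+$", body)))
      grcs_abort(sprintf("malformed block token in '%s'", s), "grcs_malformed_token")
    cur_chroms <- c(cur_chroms,
                    list(list(blocks = as.integer(body), circular = term == "@")))
  }
  flush()
  genomes
}

#' Write genomes in the block-list dialect
#'
#' Bit-exact inverse of [parse_genomes()]: single spaces, the terminator
#' preceded by a space, one header line per genome.
#'
#' @param genomes a `genome` or list of `genome` objects.
#' @param path optional file path; when `NULL` the text is returned.
#' @return the file content, invisibly when written to `path`.
#' @export
write_genomes <- function(genomes, path = NULL) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  out <- character(0)
  for (g in genomes) {
    nm <- if (is.null(g$name)) "genome" else g$name
    out <- c(out, paste0("> ", nm))
    for (ch in g$chromosomes) {
      out <- c(out, paste(c(ch$blocks, if (ch$circular) "@" else "$"),
                          collapse = " "))
    }
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(out, path)
  invisible(txt)
}

# ---------------------------------------------------------------------------
# Color maps
# ---------------------------------------------------------------------------

#' Construct a color map over the adjacencies of a genome
#'
#' Every adjacency of the genome, including telomeric adjacencies, must
#' carry exactly one color symbol.
#'
#' @param colors named character vector: names are canonical adjacency
#'   strings of `g`, values are color symbols.
#' @param g the `genome` the map refers to.
#' @return named character vector of class `color_map`.
#' @export
color_map <- function(colors, g) {
  adjs <- genome_to_adjacencies(g)
  if (anyDuplicated(names(colors)))
    grcs_abort(sprintf("duplicate color rows for: %s",
                       paste(unique(names(colors)[duplicated(names(colors))]),
                             collapse = ", ")),
               "grcs_color_error")
  extra <- setdiff(names(colors), adjs)
  if (length(extra))
    grcs_abort(sprintf("color row for adjacency absent from genome: %s",
                       paste(extra, collapse = ", ")),
               "grcs_color_error")
  missing <- setdiff(adjs, names(colors))
  if (length(missing))
    grcs_abort(sprintf("uncolored adjacency: %s", paste(missing, collapse = ", ")),
               "grcs_color_error")
  if (any(!nzchar(colors)) || any(grepl("[[:space:]]", colors)))
    grcs_abort("color symbols must be non-empty and contain no whitespace",
               "grcs_color_error")
  structure(colors[adjs], class = "color_map")
}

#' Alphabet of a color map
#' @param col a `color_map`.
#' @return sorted character vector of distinct color symbols.
#' @export
color_alphabet <- function(col) sort(unique(unname(unclass(col))))

#' Parse an adjacency color map from TSV text
#'
#' Expects a header line `adjacency<TAB>color` followed by one row per
#' adjacency of `g` in canonical string form (e.g. `5h-1h`, `5t-$`).
#'
#' @param text TSV content (scalar string or vector of lines).
#' @param g the `genome` whose adjacencies are colored.
#' @return a `color_map`.
#' @export
parse_color_map <- function(text, g) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]], c("adjacency", "color")))
    grcs_abort("color map must start with header 'adjacency\\tcolor'",
               "grcs_color_error")
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- vapply(rows, function(r) length(r) != 2, logical(1))
  if (any(bad))
    grcs_abort("color map rows must have exactly two tab-separated fields",
               "grcs_color_error")
  cols <- vapply(rows, `[`, character(1), 2)
  names(cols) <- vapply(rows, `[`, character(1), 1)
  color_map(cols, g)
}

#' Write a color map as TSV
#' @param col a `color_map`.
#' @param path optional output path.
#' @return TSV text, invisibly when written to `path`.
#' @export
write_color_map <- function(col, path = NULL) {
  out <- c("adjacency\tcolor", paste(names(col), unclass(col), sep = "\t"))
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(out, path)
  invisible(txt)
}
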