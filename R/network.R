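#' Construct a directed network
#'
#' The structural substrate used throughout the package: `n_nodes` nodes
#' labelled `0 ... n_nodes - 1` and a set of ordered links `(tail, head)`
#' meaning `tail -> head`. Self-loops and duplicate links are disallowed.
#' Reciprocal pairs (both `i -> j` and `j -> i`) are absent from networks
#' built by [generate_directed_er()]; imported edge lists may contain them,
#' in which case they are kept and counted (see [read_edge_list()]).
#'
#' @param n_nodes positive integer number of nodes.
#' @param tail,head integer vectors of equal length with 0-based node ids;
#'   link `k` runs from `tail[k]` to `head[k]`.
#' @param check validate invariants (default `TRUE`).
#' @return an object of class `directed_network`: a list with elements
#'   `n_nodes`, `tail`, `head`.
#' @examples
#' net <- directed_network(3, tail = c(0, 1, 2), head = c(1, 2, 0))
#' net
#' @export
directed_network <- function(n_nodes, tail = integer(), head = integer(),
                             check = TRUE) {
  n_nodes <- as.integer(n_nodes)
  tail <- as.integer(tail)
  head <- as.integer(head)
  if (check) {
    if (is.na(n_nodes) || n_nodes < 1L)
      stop("`n_nodes` must be a positive integer", call. = FALSE)
    if (length(tail) != length(head))
      stop("`tail` and `head` must have equal length", call. = FALSE)
    if (length(tail) > 0) {
      if (anyNA(tail) || anyNA(head))
        stop("links must not contain NA", call. = FALSE)
      if (min(tail, head) < 0L || max(tail, head) >= n_nodes)
        stop("node ids must lie in 0 ... n_nodes - 1", call. = FALSE)
      if (any(tail == head))
        stop("self-loops are not allowed", call. = FALSE)
      key <- as.double(tail) * n_nodes + head
      if (anyDuplicated(key))
        stop("duplicate directed links are not allowed", call. = FALSE)
    }
  }
  structure(list(n_nodes = n_nodes, tail = tail, head = head),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat(sprintf("<directed_network> %d nodes, %d links (mean in-degree %.4g)\n",
              x$n_nodes, length(x$tail),
              if (x$n_nodes > 0) length(x$tail) / x$n_nodes else 0))
  rec <- attr(x, "reciprocal_pairs")
  if (!is.null(rec) && rec > 0)
    cat(sprintf("  contains %d reciprocal pair(s)\n", rec))
  invisible(x)
}

#' Number of links in a directed network
#' @param net a `directed_network`.
#' @return integer link count.
#' @export
n_links <- function(net) length(net$tail)

#' In- and out-degree sequences
#'
#' @param net a `directed_network`.
#' @return integer vector of length `n_nodes` (index `i + 1` holds the
#'   degree of node `i`).
#' @export
in_degrees <- function(net) tabulate(net$head + 1L, nbins = net$n_nodes)

#' @rdname in_degrees
#' @export
out_degrees <- function(net) tabulate(net$tail + 1L, nbins = net$n_nodes)

#' Convert a directed network to an igraph graph
#'
#' Vertex `i + 1` of the igraph object corresponds to node `i`.
#'
#' @param net a `directed_network`.
#' @return an [igraph][igraph::make_graph] directed graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  edges <- rbind(net$tail + 1L, net$head + 1L)
  igraph::make_graph(edges = as.vector(edges), n = net$n_nodes,
                     directed = TRUE)
}

# map linear indices t (1-based, double-safe) over the ordered pairs
# (i, j), i < j, enumerated row-major (i = 0: j = 1..n-1; i = 1: ...)
# back to the pair. Used by both ER samplers.
pair_from_index <- function(t, n) {
  sizes <- as.double((n - 1):1)
  cum <- c(0, cumsum(sizes))          # cum[r + 1] = pairs in rows < r
  row <- findInterval(t - 0.5, cum)   # 1-based row index, i = row - 1
  i <- row - 1L
  j <- as.integer(i + (t - cum[row]))
  list(i = as.integer(i), j = j)
}

#' Generate a directed Erdos-Renyi network without reciprocal links
#'
#' An undirected skeleton is drawn by connecting each of the
#' `choose(n, 2)` labelled node pairs independently with probability
#' `2 * mean_in_degree / (n_nodes - 1)`; each undirected link `i -- j`
#' (with `i < j`) is then oriented `i -> j` and reversed with probability
#' 1/2. The construction yields, in expectation, `n_nodes * mean_in_degree`
#' links, Poisson in- and out-degrees in the sparse limit, and no
#' reciprocal pairs by construction.
#'
#' Two distributionally identical samplers are provided: an explicit
#' pairwise-Bernoulli draw over all pairs (used for `n_nodes <= 3000`),
#' and a geometric-skip sampler that jumps between successive present
#' pairs (used for larger networks, where materializing all pairs is
#' wasteful). Both consume the Mersenne-Twister stream seeded with `seed`:
#' first the skeleton draws in sorted-pair order, then one Bernoulli(1/2)
#' orientation draw per link, again in sorted-pair order. Identical
#' `(n_nodes, mean_in_degree, seed, method)` reproduce the identical
#' network.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param mean_in_degree target mean in-degree `<q_in>` (= mean out-degree).
#' @param seed integer RNG seed.
#' @param method `"auto"` (default), `"bernoulli"`, or `"skip"`.
#' @return a [directed_network()].
#' @examples
#' net <- generate_directed_er(1000, mean_in_degree = 1.5, seed = 1)
#' mean(in_degrees(net))
#' @export
generate_directed_er <- function(n_nodes, mean_in_degree, seed,
                                 method = c("auto", "bernoulli", "skip")) {
  method <- match.arg(method)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L)
    stop("`n_nodes` must be an integer >= 2", call. = FALSE)
  if (mean_in_degree < 0)
    stop("`mean_in_degree` must be nonnegative", call. = FALSE)
  p <- 2 * mean_in_degree / (n_nodes - 1)
  if (p > 1)
    stop(sprintf(
      "link probability 2 * %g / (%d - 1) = %.4g exceeds 1; increase n_nodes or lower mean_in_degree",
      mean_in_degree, n_nodes, p), call. = FALSE)
  if (method == "auto") method <- if (n_nodes <= 3000L) "bernoulli" else "skip"

  with_seed(seed, {
    m_pairs <- as.double(n_nodes) * (n_nodes - 1) / 2
    if (p == 0) {
      idx <- double(0)
    } else if (method == "bernoulli") {
      idx <- which(stats::runif(m_pairs) < p)
    } else {
      # geometric-skip: gaps between successive present pairs are
      # Geometric(p); cumulate until the pair index range is exhausted
      idx <- double(0)
      cur <- 0
      batch <- max(1000L, ceiling(1.3 * m_pairs * p) + 10L)
      while (cur < m_pairs) {
        gaps <- stats::rgeom(batch, p)
        pos <- cur + cumsum(as.double(gaps) + 1)
        keep <- pos <= m_pairs
        idx <- c(idx, pos[keep])
        if (!all(keep)) break
        cur <- pos[length(pos)]
      }
    }
    pr <- pair_from_index(idx, n_nodes)
    # orientation: i -> j, reversed with probability 1/2, sorted-pair order
    rev <- stats::runif(length(idx)) < 0.5
    tail <- ifelse(rev, pr$j, pr$i)
    head <- ifelse(rev, pr$i, pr$j)
    directed_network(n_nodes, as.integer(tail), as.integer(head),
                     check = FALSE)
  })
}

#' Read a directed edge list from a plain-text file
#'
#' Expects one whitespace-separated `tail head` integer pair per line;
#' lines starting with `#` and blank lines are ignored. Node ids are
#' remapped to `0 ... n - 1` (the mapping is returned in the `id_map`
#' attribute, `id_map[k]` being the original id of node `k - 1`).
#' Duplicate links are collapsed with a warning carrying the count;
#' reciprocal pairs are preserved and counted in the `reciprocal_pairs`
#' attribute; self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param one_based if `TRUE`, ids in the file are 1-based and shifted
#'   down on read.
#' @return a [directed_network()] with attributes `id_map`,
#'   `duplicate_links`, `reciprocal_pairs`.
#' @export
read_edge_list <- function(path, one_based = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    stop(sprintf("empty edge list: %s", path), call. = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, function(t)
    length(t) != 2L || !all(grepl("^-?[0-9]+$", t)), logical(1)))
  if (length(bad) > 0)
    stop(sprintf("cannot parse edge list %s at line %d: '%s'",
                 path, lineno[bad[1]], lines[bad[1]]), call. = FALSE)
  tails <- as.integer(vapply(toks, `[`, character(1), 1L))
  heads <- as.integer(vapply(toks, `[`, character(1), 2L))
  if (one_based) {
    tails <- tails - 1L
    heads <- heads - 1L
  }
  ids <- sort(unique(c(tails, heads)))
  tails <- match(tails, ids) - 1L
  heads <- match(heads, ids) - 1L
  n <- length(ids)

  loops <- tails == heads
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
    tails <- tails[!loops]; heads <- heads[!loops]
  }
  key <- as.double(tails) * n + heads
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(sprintf("collapsed %d duplicate link(s)", n_dup), call. = FALSE)
    tails <- tails[!dup]; heads <- heads[!dup]
    key <- key[!dup]
  }
  n_rec <- sum(key %in% (as.double(heads) * n + tails)) / 2

  net <- directed_network(n, tails, heads, check = FALSE)
  attr(net, "id_map") <- ids
  attr(net, "duplicate_links") <- n_dup
  attr(net, "reciprocal_pairs") <- as.integer(n_rec)
  net
}

#' Write a directed network as a plain-text edge list
#'
#' Inverse of [read_edge_list()] (0-based ids, one `tail head` pair per
#' line).
#'
#' @param net a `directed_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "directed_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# directed edge list: %d nodes, %d links",
                     net$n_nodes, n_links(net)), con)
  if (n_links(net) > 0)
    writeLines(paste(net$tail, net$head), con)
  invisible(path)
}

#' Induced subnetwork on a node set
#'
#' Keeps only `nodes` and the links among them; ids are remapped to
#' `0 ... length(nodes) - 1` in increasing order of the original id
#' (mapping in the `id_map` attribute).
#'
#' @param net a `directed_network`.
#' @param nodes 0-based node ids to keep.
#' @return a `directed_network`.
#' @export
induced_subnetwork <- function(net, nodes) {
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) == 0) stop("`nodes` must be nonempty", call. = FALSE)
  if (min(nodes) < 0L || max(nodes) >= net$n_nodes)
    stop("`nodes` out of range", call. = FALSE)
  keep <- net$tail %in% nodes & net$head %in% nodes
  sub <- directed_network(length(nodes),
                          match(net$tail[keep], nodes) - 1L,
                          match(net$head[keep], nodes) - 1L,
                          check = FALSE)
  attr(sub, "id_map") <- nodes
  sub
}

# CSR of in-neighbours: for node i (0-based), the in-neighbour ids are
# idx[(ptr[i + 1] + 1):ptr[i + 2]] (0-based values). Consumed by the
# C++ dynamics kernels.
in_neighbor_csr <- function(net) {
  ord <- order(net$head, net$tail)
  counts <- tabulate(net$head + 1L, nbins = net$n_nodes)
  list(ptr = c(0L, cumsum(counts)), idx = net$tail[ord])
}
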