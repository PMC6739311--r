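BOWTIE_CLASSES <- c("CORE", "IN", "OUT", "TENDRIL_FROM_IN",
                    "TENDRIL_TO_OUT", "TUBE", "DISCONNECTED")

#' Largest strongly connected component (the CORE)
#'
#' Returns the node set of the largest strongly connected component
#' (SCC) of a directed network: the largest set of nodes mutually
#' reachable through directed paths. Ties in size are broken by choosing
#' the component containing the smallest node id, so the result is
#' deterministic on tiny test graphs (the ensembles studied here never
#' tie at scale). Computation is delegated to igraph's iterative SCC
#' routine, which is recursion-safe on chain-like structures at
#' `n = 1e5`.
#'
#' @param net a [directed_network()].
#' @return sorted integer vector of 0-based node ids (a singleton for
#'   acyclic networks).
#' @examples
#' find_core(directed_network(3, c(0, 1, 2), c(1, 2, 0)))
#' @export
find_core <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  comp <- igraph::components(as_igraph(net), mode = "strong")
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    # tie-break: component holding the smallest node id
    first_member <- vapply(biggest, function(k)
      min(which(comp$membership == k)), integer(1))
    biggest <- biggest[which.min(first_member)]
  }
  sort(which(comp$membership == biggest)) - 1L
}

#' Bow-tie decomposition of a directed network
#'
#' Classifies every node into exactly one of seven classes defined
#' relative to the CORE (the largest SCC):
#' \describe{
#'   \item{CORE}{largest strongly connected component.}
#'   \item{IN}{not in the CORE, but the CORE is reachable from it.}
#'   \item{OUT}{not in the CORE, but reachable from the CORE.}
#'   \item{TUBE}{remaining nodes reachable from IN that also reach OUT.}
#'   \item{TENDRIL_FROM_IN}{remaining nodes reachable from IN only.}
#'   \item{TENDRIL_TO_OUT}{remaining nodes that reach OUT only.}
#'   \item{DISCONNECTED}{none of the above.}
#' }
#' SOURCE nodes are IN nodes with in-degree 0 and SINK nodes are OUT
#' nodes with out-degree 0. Nodes with in-degree 0 that do not reach the
#' CORE are tendrils or disconnected, not sources.
#'
#' @param net a [directed_network()].
#' @return an object of class `bowtie_partition`: list with `n_nodes`,
#'   `class_of` (character vector, node `i` at index `i + 1`), node-id
#'   vectors `core`, `in_set`, `out_set`, `sources`, `sinks`, and the
#'   named size table `sizes`.
#' @examples
#' net <- directed_network(4, c(0, 1, 2, 3), c(1, 2, 0, 0))
#' bowtie_decompose(net)
#' @export
bowtie_decompose <- function(net) {
  stopifnot(inherits(net, "directed_network"))
  n <- net$n_nodes
  core <- find_core(net)
  g <- as_igraph(net)
  rep_v <- core[1] + 1L  # any core vertex represents the whole SCC
  reach_from_core <- as.integer(igraph::subcomponent(g, rep_v, mode = "out")) - 1L
  reach_to_core <- as.integer(igraph::subcomponent(g, rep_v, mode = "in")) - 1L
  cls <- rep("DISCONNECTED", n)
  cls[reach_from_core + 1L] <- "OUT"
  cls[reach_to_core + 1L] <- "IN"
  cls[core + 1L] <- "CORE"
  in_set <- which(cls == "IN") - 1L
  out_set <- which(cls == "OUT") - 1L
  rest <- which(cls == "DISCONNECTED") - 1L

  if (length(rest) > 0) {
    from_in <- reachable_from_set(g, n, in_set, mode = "out")
    to_out <- reachable_from_set(g, n, out_set, mode = "in")
    a <- rest %in% from_in
    b <- rest %in% to_out
    cls[rest[a & b] + 1L] <- "TUBE"
    cls[rest[a & !b] + 1L] <- "TENDRIL_FROM_IN"
    cls[rest[!a & b] + 1L] <- "TENDRIL_TO_OUT"
  }

  qin <- in_degrees(net)
  qout <- out_degrees(net)
  sources <- in_set[qin[in_set + 1L] == 0L]
  sinks <- out_set[qout[out_set + 1L] == 0L]
  sizes <- table(factor(cls, levels = BOWTIE_CLASSES))
  structure(list(n_nodes = n, class_of = cls, core = core,
                 in_set = in_set, out_set = out_set,
                 sources = sources, sinks = sinks,
                 sizes = sizes),
            class = "bowtie_partition")
}

# nodes reachable from (mode = "out") or reaching (mode = "in") any node
# of `set`, via a virtual super-node attached to the whole set
reachable_from_set <- function(g, n, set, mode) {
  if (length(set) == 0) return(integer(0))
  v <- n + 1L
  edges <- if (mode == "out") rbind(v, set + 1L) else rbind(set + 1L, v)
  g2 <- igraph::add_edges(igraph::add_vertices(g, 1), as.vector(edges))
  out <- as.integer(igraph::subcomponent(g2, v, mode = mode)) - 1L
  out[out != n]
}

#' @export
print.bowtie_partition <- function(x, ...) {
  cat(sprintf("<bowtie_partition> %d nodes\n", x$n_nodes))
  print(x$sizes)
  cat(sprintf("  sources: %d  sinks: %d\n", length(x$sources),
              length(x$sinks)))
  invisible(x)
}

#' Census of links between bow-tie classes
#'
#' Counts every link once under the pair (class of tail, class of head).
#' The feedforward constraint of the bow-tie architecture implies zero
#' counts for OUT -> IN, OUT -> CORE and CORE -> IN.
#'
#' @param net a [directed_network()].
#' @param partition the matching [bowtie_decompose()] result.
#' @return an object of class `link_census`: list with the 7 x 7 integer
#'   matrix `counts` (rows = origin class) and `total_links`.
#' @export
link_census <- function(net, partition) {
  stopifnot(inherits(net, "directed_network"),
            inherits(partition, "bowtie_partition"))
  if (partition$n_nodes != net$n_nodes ||
      length(partition$class_of) != net$n_nodes)
    stop("partition is not consistent with this network", call. = FALSE)
  f <- factor(partition$class_of, levels = BOWTIE_CLASSES)
  counts <- table(origin = f[net$tail + 1L], destination = f[net$head + 1L])
  counts <- unclass(counts)
  structure(list(counts = counts, total_links = n_links(net)),
            class = "link_census")
}

#' @export
print.link_census <- function(x, ...) {
  cat(sprintf("<link_census> %d links\n", x$total_links))
  nz <- x$counts[rowSums(x$counts) > 0, colSums(x$counts) > 0, drop = FALSE]
  print(nz)
  invisible(x)
}

#' Count of links between two bow-tie classes
#' @param census a [link_census()] result.
#' @param from,to class names (e.g. `"IN"`, `"CORE"`).
#' @return integer count.
#' @export
census_count <- function(census, from, to) {
  stopifnot(inherits(census, "link_census"))
  as.integer(census$counts[from, to])
}

#' Ratio of external to internal mean in-degree of CORE nodes
#'
#' For an average CORE node the ratio between the mean number of in-links
#' received from IN nodes and from other CORE nodes equals
#' `L_IN-CORE / L_CORE-CORE`, a measure of the CORE's susceptibility to
#' the IN component.
#'
#' @param census a [link_census()] result.
#' @return nonnegative real.
#' @export
external_internal_ratio <- function(census) {
  l_cc <- census_count(census, "CORE", "CORE")
  if (l_cc == 0)
    stop("L_CORE-CORE = 0: ratio undefined (network below percolation)",
         call. = FALSE)
  census_count(census, "IN", "CORE") / l_cc
}

#' One-row structural summary of a directed network
#'
#' Convenience wrapper producing the per-network quantities used in the
#' structural survey: node/link counts, mean in-degree, fractions of
#' SOURCE and CORE nodes, link-class fractions and the
#' external/internal in-degree ratio (NA below percolation).
#'
#' @param net a [directed_network()].
#' @param partition optional precomputed [bowtie_decompose()] result.
#' @return a one-row `data.frame`.
#' @export
bowtie_summary <- function(net, partition = NULL) {
  if (is.null(partition)) partition <- bowtie_decompose(net)
  census <- link_census(net, partition)
  L <- census$total_links
  l_cc <- census_count(census, "CORE", "CORE")
  l_ic <- census_count(census, "IN", "CORE")
  data.frame(
    n_nodes = net$n_nodes,
    n_links = L,
    mean_in_degree = L / net$n_nodes,
    source_frac = length(partition$sources) / net$n_nodes,
    in_frac = length(partition$in_set) / net$n_nodes,
    core_frac = length(partition$core) / net$n_nodes,
    out_frac = length(partition$out_set) / net$n_nodes,
    l_in_in_over_l = if (L > 0) census_count(census, "IN", "IN") / L else NA_real_,
    l_in_core_over_l = if (L > 0) l_ic / L else NA_real_,
    l_core_core_over_l = if (L > 0) l_cc / L else NA_real_,
    ext_int_ratio = if (l_cc > 0) l_ic / l_cc else NA_real_
  )
}
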