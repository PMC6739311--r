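# small hand-built networks used across tests

three_cycle <- function() directed_network(3, c(0, 1, 2), c(1, 2, 0))

# 3-cycle CORE fed by one IN node (3 -> 0)
cycle_with_feeder <- function()
  directed_network(4, c(0, 1, 2, 3), c(1, 2, 0, 0))

# CORE {0,1,2}, IN {3}, OUT {4}, TUBE {5}, DISCONNECTED {6}
bowtie_toy <- function()
  directed_network(7,
                   tail = c(0, 1, 2, 3, 2, 3, 5),
                   head = c(1, 2, 0, 0, 4, 5, 4))

random_small_net <- function(n, p, seed) {
  with_seed <- getFromNamespace("with_seed", "bowtiedyn")
  with_seed(seed, {
    pairs <- expand.grid(tail = 0:(n - 1), head = 0:(n - 1))
    pairs <- pairs[pairs$tail != pairs$head, ]
    keep <- stats::runif(nrow(pairs)) < p
    directed_network(n, pairs$tail[keep], pairs$head[keep])
  })
}

# ---- independent brute-force oracle for the bow-tie classification ----
# transitive closure by boolean matrix powering; reflexive by convention
reach_closure <- function(net) {
  n <- net$n_nodes
  R <- diag(n) > 0
  if (n_links(net) > 0)
    R[cbind(net$tail + 1L, net$head + 1L)] <- TRUE
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) return(R)
    R <- R2
  }
}

brute_bowtie <- function(net) {
  n <- net$n_nodes
  R <- reach_closure(net)
  mutual <- R & t(R)
  comp_id <- match(apply(mutual, 1, paste, collapse = ""),
                   unique(apply(mutual, 1, paste, collapse = "")))
  sizes <- table(comp_id)
  largest <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(largest) > 1)
    largest <- largest[which.min(vapply(largest, function(k)
      min(which(comp_id == k)), integer(1)))]
  core <- which(comp_id == largest) - 1L

  cls <- rep("DISCONNECTED", n)
  reaches_core <- apply(R[, core + 1L, drop = FALSE], 1, any)
  reached_from_core <- apply(R[core + 1L, , drop = FALSE], 2, any)
  cls[reached_from_core] <- "OUT"
  cls[reaches_core] <- "IN"
  cls[core + 1L] <- "CORE"
  in_set <- which(cls == "IN") - 1L
  out_set <- which(cls == "OUT") - 1L
  rest <- which(cls == "DISCONNECTED") - 1L
  for (v in rest) {
    from_in <- length(in_set) > 0 && any(R[in_set + 1L, v + 1L])
    to_out <- length(out_set) > 0 && any(R[v + 1L, out_set + 1L])
    cls[v + 1L] <- if (from_in && to_out) "TUBE"
      else if (from_in) "TENDRIL_FROM_IN"
      else if (to_out) "TENDRIL_TO_OUT"
      else "DISCONNECTED"
  }
  qin <- in_degrees(net)
  qout <- out_degrees(net)
  list(class_of = cls, core = core,
       sources = in_set[qin[in_set + 1L] == 0L],
       sinks = out_set[qout[out_set + 1L] == 0L])
}
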