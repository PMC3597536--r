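# Independent oracles and shared fixtures for the suite.

# Brute-force cluster counting: depth-first search over an explicit
# adjacency list, counting connected same-state components of >= 2
# cells. Independent of the igraph-based implementation.
dfs_cluster_count <- function(ids, states, from, to, state) {
  n <- length(ids)
  adj <- vector("list", n)
  fi <- match(from, ids); ti <- match(to, ids)
  for (k in seq_along(fi)) {
    adj[[fi[k]]] <- c(adj[[fi[k]]], ti[k])
    adj[[ti[k]]] <- c(adj[[ti[k]]], fi[k])
  }
  seen <- logical(n)
  count <- 0L
  for (s in seq_len(n)) {
    if (seen[s] || states[s] != state) next
    stack <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      for (w in adj[[v]]) {
        if (!seen[w] && states[w] == state) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    if (size >= 2) count <- count + 1L
  }
  count
}

# Random graph with random states, as a minimal aggregate-like object
# accepted by count_state_clusters()
random_state_graph <- function(n, p_edge = 0.1, p_pos = 0.5) {
  cells <- tibble::tibble(
    cell_id = seq_len(n),
    x = runif(n, 0, 100), y = runif(n, 0, 100), z = runif(n, 0, 100),
    radius = 3.3,
    state = ifelse(runif(n) < p_pos, "POS", "NEG")
  )
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                          length = 6.6)
  eb_aggregate(cells, edges = edges)
}

# Shared relaxed packings (built once per test run)
shared_packing <- local({
  cache <- list()
  function(n, seed = 101) {
    key <- paste0(n, "_", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- aggregate_cells(seed_cells(n, seed = seed),
                                       seed = seed)
    }
    cache[[key]]
  }
})

# Replace states of a packing (keeps geometry, rebuilds nothing)
with_states <- function(agg, states) {
  agg$cells$state <- states
  agg
}
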