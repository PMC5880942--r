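#' Build the random connectivity of the sensory network
#'
#' Draws the directed Bernoulli(`p`) adjacency over the three connection
#' classes of the network: E-to-E (self-connections excluded), E-to-I and
#' I-to-E. There are no I-to-I connections and no self-connections. Each
#' ordered pair is an edge independently with probability `p`.
#'
#' Edges are stored as adjacency lists over *targets* of each source neuron
#' (compressed sparse rows), the layout the simulator consumes when it
#' propagates a presynaptic spike.
#'
#' @param n_e,n_i numbers of excitatory and inhibitory neurons.
#' @param p connection probability in \[0, 1\].
#' @param seed integer seed; the graph is a pure function of
#'   `(n_e, n_i, p, seed)`. The caller's RNG state is left untouched.
#' @return an object of class `connectivity_graph` with components `ee`,
#'   `ei`, `ie`, each a list with integer vectors `ptr` (0-based offsets,
#'   length `n_source + 1`) and `idx` (1-based target indices within the
#'   target population), plus `n_e`, `n_i`, `p`, `seed`.
#' @examples
#' g <- build_connectivity(3, 1, p = 1, seed = 1)
#' edge_counts(g)   # 6 E->E, 3 E->I, 3 I->E
#' @export
build_connectivity <- function(n_e, n_i, p, seed) {
  if (n_e < 0 || n_i < 0) stop("population sizes must be >= 0")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  seed <- as.integer(seed)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  draw_class <- function(n_src, n_tgt, exclude_self) {
    ptr <- integer(n_src + 1)
    idx <- vector("list", n_src)
    for (s in seq_len(n_src)) {
      tgt <- which(stats::runif(n_tgt) < p)
      if (exclude_self) tgt <- tgt[tgt != s]
      idx[[s]] <- as.integer(tgt)
      ptr[s + 1] <- ptr[s] + length(tgt)
    }
    list(ptr = ptr, idx = unlist(idx, use.names = FALSE) %||% integer(0))
  }

  g <- structure(list(
    ee = draw_class(n_e, n_e, exclude_self = TRUE),
    ei = draw_class(n_e, n_i, exclude_self = FALSE),
    ie = draw_class(n_i, n_e, exclude_self = FALSE),
    n_e = as.integer(n_e), n_i = as.integer(n_i), p = p, seed = seed),
    class = "connectivity_graph")
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname build_connectivity
#' @param graph a `connectivity_graph`.
#' @return `edge_counts()` returns a named integer vector with the number of
#'   edges in each class.
#' @export
edge_counts <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  c(ee = length(graph$ee$idx), ei = length(graph$ei$idx),
    ie = length(graph$ie$idx))
}

#' @export
print.connectivity_graph <- function(x, ...) {
  n <- edge_counts(x)
  cat(sprintf("<connectivity_graph> %d E, %d I, p = %g (seed %d)\n",
              x$n_e, x$n_i, x$p, x$seed))
  cat(sprintf("  edges: %d E->E, %d E->I, %d I->E, 0 I->I\n",
              n["ee"], n["ei"], n["ie"]))
  invisible(x)
}
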