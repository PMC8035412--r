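# The 78-edge undirected Zachary karate-club graph (34 nodes), stored as a
# versioned in-package edge list so benchmark generation needs no lookup.

.zachary_from <- c(
  1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2, 2,
  3, 3, 3, 3, 3, 3, 3, 3, 4, 4, 4, 5, 5, 6, 6, 6, 7, 9, 9, 9, 10, 14, 15,
  15, 16, 16, 19, 19, 20, 21, 21, 23, 23, 24, 24, 24, 24, 24, 25, 25, 25,
  26, 27, 27, 28, 29, 29, 30, 30, 31, 31, 32, 32, 33)

.zachary_to <- c(
  2, 3, 4, 5, 6, 7, 8, 9, 11, 12, 13, 14, 18, 20, 22, 32, 3, 4, 8, 14, 18,
  20, 22, 31, 4, 8, 28, 29, 33, 10, 9, 14, 8, 13, 14, 7, 11, 7, 11, 17, 17,
  31, 33, 34, 34, 34, 33, 34, 33, 34, 33, 34, 34, 33, 34, 33, 34, 26, 28,
  33, 34, 30, 26, 28, 32, 32, 30, 34, 34, 32, 34, 33, 34, 33, 34, 33, 34,
  34)

#' Zachary karate-club edge list
#'
#' Returns the standard 34-node, 78-edge undirected karate-club graph as a
#' two-column matrix of node indices.
#'
#' @return Integer matrix, 78 x 2.
#' @export
zachary_edges <- function() {
  cbind(from = as.integer(.zachary_from), to = as.integer(.zachary_to))
}
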