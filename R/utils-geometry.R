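# Small geometry helpers shared by the engine and the distance profiles.

coords_matrix <- function(structure, subset = NULL) {
  at <- structure$atoms
  if (!is.null(subset)) at <- at[subset, , drop = FALSE]
  cbind(at$x, at$y, at$z)
}

# Full pairwise Euclidean distance matrix for an n x 3 coordinate matrix.
pair_dist <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

# n x m cross-distance matrix between two coordinate matrices.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

min_cross_dist <- function(a, b) min(cross_dist(a, b))
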