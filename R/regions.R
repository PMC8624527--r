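#' Region structure of a piecewise-affine model
#'
#' Local models act on polyhedral regions of regressor space. Only regions
#' whose clusters are adjacent (by the nearest-neighbor rule on cluster
#' centers) get a dividing surface, which is why a 3-region model may list
#' surfaces for pairs (1,3) and (2,3) but not (1,2).
#'
#' @name region_partition
NULL

#' Adjacent region pairs by the nearest-center rule
#'
#' Each cluster is adjacent to the cluster whose center is nearest to its
#' own; the union of these relations, deduplicated and sorted, is returned.
#'
#' @param centers Matrix of cluster centers (rows).
#' @return Integer matrix with columns `i`, `j` (i < j); zero rows when
#'   fewer than 2 centers are given.
#' @export
adjacent_subspaces <- function(centers) {
  centers <- as.matrix(centers)
  S <- nrow(centers)
  if (S < 2L) {
    pwa_log("fewer than 2 centers: no dividing surfaces needed")
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  d2 <- as.matrix(stats::dist(centers))^2
  diag(d2) <- Inf
  pairs <- do.call(rbind, lapply(seq_len(S), function(i) {
    dmin <- min(d2[i, ])
    # all centers tied for nearest (within numerical tolerance) are adjacent
    js <- which(d2[i, ] <= dmin * (1 + 1e-12))
    t(vapply(js, function(j) sort(c(i, j)), integer(2)))
  }))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' Train dividing surfaces between adjacent regions
#'
#' For each adjacent pair (i, j), a linear-kernel LS-SVM is trained on the
#' regressor vectors of the two clusters (+1 for region i, -1 for region j)
#' and its hyperplane extracted.
#'
#' @param X Matrix of regressor vectors (rows).
#' @param labels Cluster labels per row.
#' @param centers Cluster centers used for the adjacency rule (z-space
#'   centers are fine; only their relative distances matter).
#' @param lssvm_gamma Penalty weight passed to [lssvm_solve()].
#' @return List of `dividing_surface` objects.
#' @export
build_surfaces <- function(X, labels, centers, lssvm_gamma = 10) {
  pairs <- adjacent_subspaces(centers)
  apply_rows <- seq_len(nrow(pairs))
  surfaces <- lapply(apply_rows, function(k) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    idx <- which(labels %in% c(i, j))
    lab <- ifelse(labels[idx] == i, 1, -1)
    model <- lssvm_solve(X[idx, , drop = FALSE], lab, kernel = "linear",
                         lssvm_gamma = lssvm_gamma)
    extract_hyperplane(model, pair = c(i, j))
  })
  surfaces
}

#' Assign regressor vectors to regions by their dividing surfaces
#'
#' A point belongs to region i when it satisfies every surface constraint
#' involving i (value >= 0 on surfaces where i is the positive region,
#' <= 0 where it is the negative one); a boundary value of 0 satisfies both
#' sides (closed polyhedra). When several regions qualify the lowest index
#' wins; when none does (possible with pairwise-trained surfaces) the point
#' falls back to the nearest center in regressor space and the event is
#' logged.
#'
#' @param X Matrix of regressor vectors (rows), or a single vector.
#' @param surfaces List of `dividing_surface` objects.
#' @param centers Cluster centers; only their first `ncol(X)` coordinates
#'   (the regressor part) are used for the fallback rule.
#' @param S Number of regions (default: inferred from centers).
#' @return Integer vector of region indices.
#' @export
assign_region <- function(X, surfaces, centers, S = nrow(as.matrix(centers))) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (S == 1L || !length(surfaces)) return(rep(1L, nrow(X)))
  centers <- as.matrix(centers)
  centers_X <- centers[, seq_len(ncol(X)), drop = FALSE]
  ok <- matrix(TRUE, nrow(X), S)
  for (s in surfaces) {
    val <- as.numeric(X %*% s$w + s$v)
    ok[, s$pair[1]] <- ok[, s$pair[1]] & (val >= 0)
    ok[, s$pair[2]] <- ok[, s$pair[2]] & (val <= 0)
  }
  region <- integer(nrow(X))
  any_ok <- rowSums(ok) > 0
  if (any(any_ok)) {
    region[any_ok] <- max.col(ok[any_ok, , drop = FALSE], ties.method = "first")
  }
  if (any(!any_ok)) {
    pwa_log(sum(!any_ok), " points had inconsistent surface sign patterns; ",
            "falling back to nearest center")
    bad <- which(!any_ok)
    d2 <- outer(rowSums(X[bad, , drop = FALSE]^2), rep(1, S)) -
      2 * X[bad, , drop = FALSE] %*% t(centers_X) +
      outer(rep(1, length(bad)), rowSums(centers_X^2))
    region[bad] <- max.col(-d2, ties.method = "first")
  }
  region
}
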