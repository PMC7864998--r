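#' Metric multidimensional scaling of a mean distance matrix
#'
#' Embeds the gradings into the plane so that pairwise Euclidean distances
#' reproduce the mean Hamming distances as accurately as possible. The
#' solution is Torgerson classical scaling (double centering) refined by
#' SMACOF-style stress majorization, which never increases stress, iterated
#' until the relative stress change falls below `tol` or `max_iter`
#' iterations. Axes are unitless and on the Hamming scale.
#'
#' Because an embedding is defined only up to rigid motion, the result is
#' canonicalized: coordinates are centered at the origin, rotated so the
#' first grading lies on the non-negative x-axis, and reflected so the
#' second grading has non-negative y. This makes outputs comparable across
#' runs.
#'
#' @param d A symmetric, zero-diagonal, non-negative distance matrix with
#'   dimnames (e.g. a [mean_distance_matrix()]), k >= 2.
#' @param seed Integer recorded in the result; the algorithm itself is
#'   deterministic.
#' @param tol Relative stress-change convergence threshold.
#' @param max_iter Maximum majorization iterations.
#' @return An `embedding2d`: list with `ids`, `coords` (k x 2 matrix),
#'   `stress` (Kruskal raw stress), `n_iter`, and `seed`.
#' @export
mds_embed <- function(d, seed = 0L, tol = 1e-9, max_iter = 300L) {
  d <- check_distance_matrix(d)
  k <- nrow(d)
  ids <- rownames(d)
  if (all(d == 0)) {
    emb <- structure(list(ids = ids, coords = matrix(0, k, 2,
                            dimnames = list(ids, c("x", "y"))),
                          stress = 0, n_iter = 0L, seed = as.integer(seed)),
                     class = "embedding2d")
    return(emb)
  }
  x <- suppressWarnings(stats::cmdscale(d, k = min(2L, k - 1L)))
  if (ncol(x) < 2L) x <- cbind(x, matrix(0, k, 2L - ncol(x)))
  s <- raw_stress(d, x)
  iter <- 0L
  while (iter < max_iter) {
    x_new <- guttman_transform(d, x)
    s_new <- raw_stress(d, x_new)
    iter <- iter + 1L
    done <- s < tol || (s - s_new) < tol * max(s, .Machine$double.eps)
    x <- x_new; s <- s_new
    if (done) break
  }
  x <- canonicalize_coords(x)
  dimnames(x) <- list(ids, c("x", "y"))
  structure(list(ids = ids, coords = x, stress = raw_stress(d, x),
                 n_iter = iter, seed = as.integer(seed)),
            class = "embedding2d")
}

check_distance_matrix <- function(d) {
  d <- unclass(as.matrix(d))
  if (nrow(d) != ncol(d) || nrow(d) < 2L)
    stop("distance matrix must be square with k >= 2")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("g", seq_len(nrow(d)))
  d
}

euclid_dists <- function(x) as.matrix(stats::dist(x))

# One majorization step (Guttman transform, unit weights): X' = k^-1 B(X) X.
guttman_transform <- function(d, x) {
  k <- nrow(x)
  dx <- euclid_dists(x)
  ratio <- ifelse(dx > 0, d / dx, 0)
  b <- -ratio
  diag(b) <- 0
  diag(b) <- -rowSums(b)
  (b %*% x) / k
}

#' Kruskal raw stress of an embedding
#'
#' `sqrt( sum_{i<j} (d_ij - ||x_i - x_j||)^2 / sum_{i<j} d_ij^2 )`; zero iff
#' the embedding reproduces the distances exactly.
#'
#' @param d Distance matrix with ids as dimnames.
#' @param e An `embedding2d` (see [mds_embed()]) or a coordinate matrix with
#'   matching row order.
#' @return Non-negative scalar.
#' @export
stress <- function(d, e) {
  d <- check_distance_matrix(d)
  x <- if (inherits(e, "embedding2d")) {
    if (!identical(e$ids, rownames(d)))
      stop("embedding ids do not match distance matrix ids")
    e$coords
  } else e
  raw_stress(d, x)
}

raw_stress <- function(d, x) {
  dx <- euclid_dists(x)
  up <- upper.tri(d)
  denom <- sum(d[up]^2)
  if (denom == 0) return(if (all(dx[up] == 0)) 0 else Inf)
  sqrt(sum((d[up] - dx[up])^2) / denom)
}

canonicalize_coords <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  v <- x[1, ]
  if (sqrt(sum(v^2)) > 1e-12) {
    theta <- atan2(v[2], v[1])
    # row-vector convention: x %*% R(theta) rotates every point by -theta
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    x <- x %*% rot
  }
  if (nrow(x) >= 2L && x[2, 2] < 0) x[, 2] <- -x[, 2]
  x
}

#' @export
print.embedding2d <- function(x, digits = 4, ...) {
  cat(sprintf("<embedding2d: %d gradings, stress %.3g (%d iterations)>\n",
              length(x$ids), x$stress, x$n_iter))
  print(round(x$coords, digits))
  invisible(x)
}

#' Write embedding coordinates to CSV
#'
#' Columns `grading_id,x,y`, followed by a comment footer line
#' `# stress=<value>`.
#'
#' @param e An `embedding2d`.
#' @param path Output CSV path.
#' @export
write_embedding <- function(e, path) {
  df <- data.frame(grading_id = e$ids, x = e$coords[, 1], y = e$coords[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  cat(sprintf("# stress=%.12g\n", e$stress), file = path, append = TRUE)
  invisible(path)
}

#' Plot a 2D grading embedding
#'
#' Graders are drawn as black triangles, the model (if identified) as a red
#' circle, matching the field's usual presentation of grader-model MDS maps.
#'
#' @param x An `embedding2d`.
#' @param model_id Optional id to highlight as the model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.embedding2d <- function(x, model_id = NULL, ...) {
  is_model <- if (is.null(model_id)) rep(FALSE, length(x$ids)) else x$ids == model_id
  rng <- range(x$coords)
  pad <- 0.15 * max(diff(rng), .Machine$double.eps)
  graphics::plot(x$coords, asp = 1, xlim = rng + c(-pad, pad),
                 ylim = rng + c(-pad, pad),
                 pch = ifelse(is_model, 19, 17),
                 col = ifelse(is_model, "red", "black"),
                 xlab = "dimension 1 (Hamming scale)",
                 ylab = "dimension 2 (Hamming scale)", ...)
  graphics::text(x$coords, labels = x$ids, pos = 3, cex = 0.8)
  invisible(x)
}
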