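#' Distance scopes
#'
#' Pairwise gradings are compared either across all compartments at once
#' (`"all"`, the 4-way label comparison) or per compartment (binary-map
#' comparison). The denominator is always the total pixel count, so the four
#' per-compartment distances of a pair sum to exactly twice the overall
#' distance (each differing pixel flips two binary maps).
#'
#' @format Character vector of the five scope names.
#' @export
SCOPES <- c("all", names(COMPARTMENTS))

check_scope <- function(scope) {
  scope <- tolower(as.character(scope))
  if (length(scope) != 1L || !scope %in% SCOPES)
    stop("scope must be one of ", paste(SCOPES, collapse = ", "))
  scope
}

#' Hamming distance between two segmentations
#'
#' The proportion of pixels labeled differently between two label maps of
#' the same scan; equal to one minus the pixel accuracy. A metric in the
#' mathematical sense: non-negative, zero iff identical, symmetric, and
#' satisfying the triangle inequality.
#'
#' @param a,b [labelmap()] objects (or plain integer matrices) of the same
#'   shape.
#' @return A fraction in `[0, 1]`.
#' @export
hamming <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  mean(unclass(a) != unclass(b))
}

#' Per-compartment Hamming distance
#'
#' Hamming distance between the binary membership maps of one compartment
#' (see [labelmap_to_binary()]). The denominator is the total pixel count of
#' the image, not the compartment size.
#'
#' @inheritParams hamming
#' @param compartment Compartment name or code.
#' @return A fraction in `[0, 1]`.
#' @export
compartment_hamming <- function(a, b, compartment) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %dx%d vs %dx%d",
                 nrow(a), ncol(a), nrow(b), ncol(b)))
  code <- compartment_code(compartment)
  mean((unclass(a) == code) != (unclass(b) == code))
}

scoped_distance <- function(a, b, scope) {
  if (scope == "all") hamming(a, b) else compartment_hamming(a, b, scope)
}

#' Per-scan pairwise distance table
#'
#' Computes, for every scan and every requested pair of gradings, the
#' Hamming distance at each requested scope. This table is the substrate of
#' all downstream summaries: mean matrices, boxplots, the neural-recording
#' heatmap, and the permutation test.
#'
#' @param e A [grading_ensemble()].
#' @param pairs A list of length-2 character vectors of grading ids, or
#'   `NULL` for all unordered pairs among graders plus model.
#' @param scopes Character vector of scopes (subset of [SCOPES]).
#' @return A `distance_table`: a data frame with columns `scan_id`,
#'   `grading_a`, `grading_b`, `scope`, `distance`. Pairs are stored once in
#'   the order given; the distance is symmetric in the pair.
#' @export
build_distance_table <- function(e, pairs = NULL, scopes = "all") {
  stopifnot(inherits(e, "grading_ensemble"))
  all_ids <- c(e$grader_ids, e$model_id)
  if (is.null(pairs)) {
    pairs <- utils::combn(all_ids, 2L, simplify = FALSE)
  }
  scopes <- vapply(scopes, check_scope, "")
  rows <- vector("list", length(e$scan_ids) * length(pairs))
  k <- 0L
  for (s in e$scan_ids) {
    for (p in pairs) {
      a <- ensemble_map(e, s, p[1]); b <- ensemble_map(e, s, p[2])
      d <- vapply(scopes, function(sc) scoped_distance(a, b, sc), 0)
      k <- k + 1L
      rows[[k]] <- data.frame(scan_id = s, grading_a = p[1], grading_b = p[2],
                              scope = unname(scopes), distance = unname(d),
                              stringsAsFactors = FALSE)
    }
  }
  t <- do.call(rbind, rows)
  rownames(t) <- NULL
  class(t) <- c("distance_table", "data.frame")
  t
}

#' Read and write distance tables
#'
#' CSV serialization with header `scan_id,grading_a,grading_b,scope,distance`.
#'
#' @param t A `distance_table` (see [build_distance_table()]).
#' @param path CSV file path.
#' @export
write_distance_table <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "grading_a", "grading_b", "scope", "distance")
  if (!all(need %in% names(t)))
    stop("distance CSV must have columns ", paste(need, collapse = ","))
  if (any(t$distance < 0 | t$distance > 1))
    stop("distances must lie in [0, 1]")
  class(t) <- c("distance_table", "data.frame")
  t
}

# rows of t for an unordered pair at one scope
pair_rows <- function(t, a, b, scope) {
  t[t$scope == scope &
      ((t$grading_a == a & t$grading_b == b) |
       (t$grading_a == b & t$grading_b == a)), , drop = FALSE]
}

#' Mean distance matrix over scans
#'
#' Entry (i, j) is the mean over scans of the pairwise Hamming distance
#' between gradings i and j at the given scope. Symmetric with a zero
#' diagonal; since every per-scan distance is a metric, the mean is too.
#'
#' @param t A `distance_table`.
#' @param scope One of [SCOPES].
#' @param ids Ordered grading ids; default: order of appearance in `t`.
#' @return A `mean_distance_matrix`: a k x k numeric matrix with `ids` as
#'   dimnames and attributes `scope` and `n_scans`.
#' @export
mean_distance_matrix <- function(t, scope = "all", ids = NULL) {
  scope <- check_scope(scope)
  if (is.null(ids)) ids <- unique(c(rbind(t$grading_a, t$grading_b)))
  k <- length(ids)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  scan_sets <- NULL
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rows <- pair_rows(t, ids[i], ids[j], scope)
    if (nrow(rows) == 0L)
      stop(sprintf("no %s-scope records for pair (%s, %s)",
                   scope, ids[i], ids[j]))
    scans <- sort(unique(rows$scan_id))
    if (is.null(scan_sets)) scan_sets <- scans
    else if (!identical(scan_sets, scans))
      stop(sprintf("pair (%s, %s) covers a different scan set than earlier pairs",
                   ids[i], ids[j]))
    m[i, j] <- m[j, i] <- mean(rows$distance)
  }
  structure(m, scope = scope, n_scans = length(scan_sets),
            class = c("mean_distance_matrix", "matrix", "array"))
}

#' @export
print.mean_distance_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<mean_distance_matrix: scope=%s, %d scans>\n",
              attr(x, "scope"), attr(x, "n_scans")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Fraction of scans where the model is closer than the graders agree
#'
#' For each scan, compares the mean of the grader-model distances with the
#' mean of the inter-grader distances (overall scope) and reports the
#' fraction of scans where the model mean is strictly smaller. Ties count as
#' not-closer.
#'
#' @param t A `distance_table` with overall-scope records for all
#'   inter-grader and grader-model pairs.
#' @param grader_ids Character vector of grader ids.
#' @param model_id Model grading id.
#' @return A fraction in `[0, 1]`.
#' @export
fraction_model_closer <- function(t, grader_ids, model_id) {
  gm <- group_means_per_scan(t, grader_ids, model_id, scope = "all")
  mean(gm$model_mean < gm$grader_mean)
}

# per-scan means of inter-grader and grader-model overall distances
group_means_per_scan <- function(t, grader_ids, model_id, scope = "all") {
  scope <- check_scope(scope)
  gpairs <- utils::combn(grader_ids, 2L, simplify = FALSE)
  scans <- sort(unique(t$scan_id[t$scope == scope]))
  if (length(scans) == 0L) stop("no records at scope ", scope)
  gmean <- mmean <- numeric(length(scans))
  collect <- function(pairs) {
    vals <- matrix(NA_real_, length(scans), length(pairs))
    for (j in seq_along(pairs)) {
      rows <- pair_rows(t, pairs[[j]][1], pairs[[j]][2], scope)
      idx <- match(scans, rows$scan_id)
      if (anyNA(idx))
        stop(sprintf("incomplete records for pair (%s, %s) at scope %s",
                     pairs[[j]][1], pairs[[j]][2], scope))
      vals[, j] <- rows$distance[idx]
    }
    vals
  }
  mpairs <- lapply(grader_ids, function(g) c(g, model_id))
  data.frame(scan_id = scans,
             grader_mean = rowMeans(collect(gpairs)),
             model_mean = rowMeans(collect(mpairs)),
             stringsAsFactors = FALSE)
}

#' Pooled group means
#'
#' Pools all inter-grader distances (group A) and all grader-model distances
#' (group B) at one scope and returns their means, the headline aggregate of
#' a grading-variability study (e.g. mean inter-grader vs grader-model
#' overall Hamming distance).
#'
#' @inheritParams fraction_model_closer
#' @param scope One of [SCOPES].
#' @return Named list with `inter_grader` and `grader_model` means
#'   (fractions).
#' @export
pooled_group_means <- function(t, grader_ids, model_id, scope = "all") {
  g <- assemble_groups(t, grader_ids, model_id, scope)
  list(inter_grader = mean(g$group_a), grader_model = mean(g$group_b))
}
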