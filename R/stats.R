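#' Assemble inter-grader and grader-model distance groups
#'
#' Pools, at one scope, all inter-grader distances into group A and all
#' grader-model distances into group B. With 3 graders and N scans each
#' group has 3N values (e.g. 600 for a 200-scan test set). Order is stable:
#' pairs in combination order, scans in table order within pair.
#'
#' @param t A `distance_table` (see [build_distance_table()]).
#' @param grader_ids Character vector of at least two grader ids.
#' @param model_id Model grading id.
#' @param scope One of [SCOPES].
#' @return A `distance_groups` list with `group_a` (inter-grader),
#'   `group_b` (grader-model), and `scope`.
#' @export
assemble_groups <- function(t, grader_ids, model_id, scope = "all") {
  scope <- check_scope(scope)
  stopifnot(length(grader_ids) >= 2L, length(model_id) == 1L)
  pull <- function(pairs) {
    unlist(lapply(pairs, function(p) {
      rows <- pair_rows(t, p[1], p[2], scope)
      if (nrow(rows) == 0L)
        stop(sprintf("no %s-scope records for pair (%s, %s)", scope, p[1], p[2]))
      rows$distance
    }))
  }
  a <- pull(utils::combn(grader_ids, 2L, simplify = FALSE))
  b <- pull(lapply(grader_ids, function(g) c(g, model_id)))
  structure(list(group_a = a, group_b = b, scope = scope),
            class = "distance_groups")
}

new_permutation_result <- function(observed, n_ge, n_le, n_total, add_one,
                                   scope = NA_character_, seed = NA_integer_) {
  corr <- as.integer(add_one)
  p_upper <- (n_ge + corr) / (n_total + corr)
  p_lower <- (n_le + corr) / (n_total + corr)
  p_two <- min(1, 2 * min(p_lower, p_upper))
  smaller <- min(n_ge, n_le)
  # Clopper-Pearson 99% interval on the smaller tail proportion, doubled
  lo <- if (smaller == 0) 0 else stats::qbeta(0.005, smaller, n_total - smaller + 1)
  hi <- if (smaller == n_total) 1 else stats::qbeta(0.995, smaller + 1, n_total - smaller)
  ci99 <- pmin(1, pmax(0, 2 * c(lo, hi)))
  structure(list(observed = observed, p_two_sided = p_two,
                 p_lower = p_lower, p_upper = p_upper,
                 n_resamples = n_total,
                 exceed_count = min(n_ge, n_le),
                 ci99 = ci99, scope = scope, seed = seed,
                 exact = !add_one),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s permutation test (%s)\n",
              if (isTRUE(x$exact)) "Exhaustive" else "Monte-Carlo",
              if (is.na(x$scope)) "unscoped" else paste0("scope: ", x$scope)))
  cat(sprintf("  observed mean difference (A - B): %.6g\n", x$observed))
  cat(sprintf("  p (two-sided) = %.3g  [p_lower = %.3g, p_upper = %.3g]\n",
              x$p_two_sided, x$p_lower, x$p_upper))
  cat(sprintf("  %d %s, %d as-or-more-extreme in the smaller tail\n",
              x$n_resamples,
              if (isTRUE(x$exact)) "distinct assignments" else "resamples",
              x$exceed_count))
  cat(sprintf("  99%% CI for p: (%.3g, %.3g)\n", x$ci99[1], x$ci99[2]))
  invisible(x)
}

#' Unpaired Monte-Carlo permutation test on a difference of means
#'
#' Tests whether two groups of distances originate from distributions with
#' different means. The statistic is `mean(group_a) - mean(group_b)`. For
#' each resample the pooled values are randomly re-split, without
#' replacement, into groups of the original sizes; resampled statistics
#' exactly equal to the observed one count as exceedances. One-sided
#' p-values use the add-one estimator `(count + 1) / (n_resamples + 1)`, so
#' the smallest attainable two-sided p is `2 / (n_resamples + 1)` — with
#' 99,999 resamples, 2e-5.
#'
#' @param g A `distance_groups` (see [assemble_groups()]), or any list with
#'   numeric `group_a` and `group_b`.
#' @param n_resamples Number of Monte-Carlo resamples (default 99999).
#' @param seed Integer seed for the resampling stream.
#' @return A `permutation_result` with elements `observed`, `p_two_sided`,
#'   `p_lower`, `p_upper`, `n_resamples`, `exceed_count`, `ci99`, `seed`.
#' @export
mc_permutation_test <- function(g, n_resamples = 99999L, seed = 1L) {
  a <- g$group_a; b <- g$group_b
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  t_obs <- mean(a) - mean(b)
  # mean_a - mean_b is affine in sum(resampled A): only S_A is needed
  s_tot <- sum(pool)
  stat_from_sa <- function(sa) sa / na - (s_tot - sa) / (n - na)
  stats_perm <- local_seed(seed, {
    vapply(seq_len(n_resamples),
           function(i) stat_from_sa(sum(pool[sample.int(n, na)])), 0)
  })
  eps <- 1e-12 * max(1, abs(t_obs))
  n_ge <- sum(stats_perm >= t_obs - eps)
  n_le <- sum(stats_perm <= t_obs + eps)
  new_permutation_result(t_obs, n_ge, n_le, n_resamples, add_one = TRUE,
                         scope = if (is.null(g$scope)) NA_character_ else g$scope,
                         seed = as.integer(seed))
}

# run expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Exhaustive permutation test (small-sample oracle)
#'
#' Enumerates all distinct assignments of the pooled values into groups of
#' the original sizes and computes exact one- and two-sided p-values for the
#' difference of means, with the same tie rule as [mc_permutation_test()]
#' but no add-one correction (the enumeration is exact). Used as the
#' correctness oracle for the Monte-Carlo test.
#'
#' @inheritParams mc_permutation_test
#' @param max_assignments Refuse to enumerate more than this many splits.
#' @return A `permutation_result` (with `exact = TRUE`).
#' @export
exhaustive_permutation_test <- function(g, max_assignments = 1e6) {
  a <- g$group_a; b <- g$group_b
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  if (choose(n, na) > max_assignments)
    stop(sprintf("C(%d, %d) exceeds the enumeration bound %g", n, na,
                 max_assignments))
  t_obs <- mean(a) - mean(b)
  s_tot <- sum(pool)
  sa <- utils::combn(n, na, function(idx) sum(pool[idx]))
  stats_perm <- sa / na - (s_tot - sa) / (n - na)
  eps <- 1e-12 * max(1, abs(t_obs))
  n_ge <- sum(stats_perm >= t_obs - eps)
  n_le <- sum(stats_perm <= t_obs + eps)
  new_permutation_result(t_obs, n_ge, n_le, length(stats_perm),
                         add_one = FALSE,
                         scope = if (is.null(g$scope)) NA_character_ else g$scope)
}

#' Boxplot summary with the IQR whisker rule
#'
#' Quartiles by linear interpolation; the upper whisker extends to the last
#' datum strictly less than `Q3 + 1.5 * IQR`, the lower whisker to the first
#' datum strictly greater than `Q1 - 1.5 * IQR`; data beyond the whiskers
#' are outliers. For degenerate (e.g. constant) data where no datum lies
#' strictly inside a fence, the whisker falls back to the quartile and no
#' outliers are flagged on that side.
#'
#' @param values Non-empty numeric vector.
#' @return A list with `q1`, `median`, `q3`, `mean`, `lower_whisker`,
#'   `upper_whisker`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) stop("values must be non-empty numeric")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  hi_fence <- q[3] + 1.5 * iqr
  lo_fence <- q[1] - 1.5 * iqr
  inside_hi <- values[values < hi_fence]
  inside_lo <- values[values > lo_fence]
  upper <- if (length(inside_hi)) max(inside_hi) else q[3]
  lower <- if (length(inside_lo)) min(inside_lo) else q[1]
  list(q1 = q[1], median = q[2], q3 = q[3], mean = mean(values),
       lower_whisker = lower, upper_whisker = upper,
       outliers = sort(values[values < lower | values > upper]))
}

#' Serialize a permutation result to JSON
#'
#' @param x A `permutation_result`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @export
permutation_result_json <- function(x, path = NULL) {
  obj <- list(scope = x$scope, observed = x$observed,
              p_two_sided = x$p_two_sided, p_lower = x$p_lower,
              p_upper = x$p_upper, n_resamples = x$n_resamples,
              exceed_count = x$exceed_count,
              ci99 = x$ci99, seed = x$seed)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
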