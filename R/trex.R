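#' Traceable relevance explainability analysis of a grading ensemble
#'
#' The package's central function. Given label maps from several graders
#' and optionally one model, it computes the full pairwise Hamming-distance
#' table (overall and per compartment), mean distance matrices, 2D metric
#' MDS embeddings, per-pair boxplot summaries, and — when a model grading is
#' present — the per-scan comparison of grader-model versus inter-grader
#' distances and the unpaired Monte-Carlo permutation test per scope.
#'
#' @param e A [grading_ensemble()], or a `distance_table` (see
#'   [build_distance_table()]) if distances were computed or loaded
#'   beforehand (then `grader_ids`/`model_id` must be given).
#' @param scopes Scopes to analyse (default all five).
#' @param n_resamples Monte-Carlo resamples for the permutation tests.
#' @param seed Integer seed driving the permutation streams.
#' @param grader_ids,model_id Only used when `e` is a `distance_table`.
#' @return An object of class `trex`: a list with elements
#'   `table` (the distance table), `mean_matrices`, `embeddings`,
#'   `boxplots` (per scope, per pair), `permutations` (per scope, or `NULL`
#'   when no model grading exists), `pooled_means`, `fraction_model_closer`,
#'   `grader_ids`, `model_id`, `scopes`, `seed`, and `notices`.
#' @seealso [summary.trex()], [plot.trex()], [write_trex_report()]
#' @examples
#' cfg <- scene_config(height = 64, width = 64, mean_rows = c(16, 34, 44),
#'                     undulation_amplitude = 3, n_scans = 5, seed = 7)
#' fit <- trex(simulate_study(cfg), n_resamples = 999)
#' fit
#' @export
trex <- function(e, scopes = SCOPES, n_resamples = 99999L, seed = 1L,
                 grader_ids = NULL, model_id = NULL) {
  scopes <- vapply(scopes, check_scope, "")
  if (inherits(e, "grading_ensemble")) {
    grader_ids <- e$grader_ids
    model_id <- e$model_id
    tab <- build_distance_table(e, scopes = scopes)
  } else if (inherits(e, "distance_table") || is.data.frame(e)) {
    if (is.null(grader_ids))
      stop("grader_ids must be supplied with a distance table")
    tab <- e
    class(tab) <- c("distance_table", "data.frame")
  } else stop("e must be a grading_ensemble or a distance_table")

  notices <- character()
  ids <- c(grader_ids, model_id)
  mean_mats <- lapply(stats::setNames(scopes, scopes), function(sc)
    mean_distance_matrix(tab, sc, ids = ids))
  embeddings <- lapply(mean_mats, mds_embed, seed = seed)
  boxplots <- lapply(stats::setNames(scopes, scopes), function(sc) {
    pairs <- utils::combn(ids, 2L, simplify = FALSE)
    out <- lapply(pairs, function(p)
      boxplot_summary(pair_rows(tab, p[1], p[2], sc)$distance))
    names(out) <- vapply(pairs, paste, "", collapse = "-")
    out
  })

  permutations <- NULL
  pooled <- NULL
  frac_closer <- NULL
  if (!is.null(model_id) && length(grader_ids) >= 2L) {
    permutations <- lapply(stats::setNames(scopes, scopes), function(sc) {
      g <- assemble_groups(tab, grader_ids, model_id, sc)
      mc_permutation_test(g, n_resamples = n_resamples,
                          seed = subseed(seed, paste0("perm/", sc)))
    })
    pooled <- lapply(stats::setNames(scopes, scopes), function(sc)
      pooled_group_means(tab, grader_ids, model_id, sc))
    if ("all" %in% scopes)
      frac_closer <- fraction_model_closer(tab, grader_ids, model_id)
  } else {
    notices <- c(notices,
                 "no model grading (or fewer than two graders): permutation stage skipped")
  }

  structure(list(table = tab, mean_matrices = mean_mats,
                 embeddings = embeddings, boxplots = boxplots,
                 permutations = permutations, pooled_means = pooled,
                 fraction_model_closer = frac_closer,
                 grader_ids = grader_ids, model_id = model_id,
                 scopes = scopes, seed = as.integer(seed),
                 n_resamples = as.integer(n_resamples),
                 notices = notices),
            class = "trex")
}

#' @export
print.trex <- function(x, ...) {
  n_scans <- length(unique(x$table$scan_id))
  cat(sprintf("T-REX analysis: %d scans, graders %s%s\n", n_scans,
              paste(x$grader_ids, collapse = ", "),
              if (is.null(x$model_id)) "" else paste0(", model ", x$model_id)))
  if ("all" %in% x$scopes) {
    m <- unclass(x$mean_matrices[["all"]]) * 100
    attributes(m)[c("scope", "n_scans")] <- NULL
    cat("Mean overall Hamming distance (%):\n")
    print(round(m, 2))
  }
  if (!is.null(x$pooled_means) && "all" %in% x$scopes) {
    pm <- x$pooled_means[["all"]]
    cat(sprintf("Pooled means (overall): inter-grader %.2f%%, grader-model %.2f%%\n",
                100 * pm$inter_grader, 100 * pm$grader_model))
  }
  if (!is.null(x$fraction_model_closer))
    cat(sprintf("Model mean distance smaller than inter-grader mean on %.1f%% of scans\n",
                100 * x$fraction_model_closer))
  if (!is.null(x$permutations)) {
    p <- vapply(x$permutations, `[[`, 0, "p_two_sided")
    cat("Permutation p (two-sided) by scope:",
        paste(sprintf("%s=%.3g", names(p), p), collapse = " "), "\n")
  }
  for (n in x$notices) cat("note:", n, "\n")
  invisible(x)
}

#' Summarize a T-REX analysis
#'
#' @param object A `trex` object.
#' @param ... Unused.
#' @return A list (class `summary.trex`) with per-scope mean matrices in
#'   percent, embedding stress values, pooled group means, the fraction of
#'   scans where the model is closer, and permutation p-values.
#' @export
summary.trex <- function(object, ...) {
  out <- list(
    n_scans = length(unique(object$table$scan_id)),
    grader_ids = object$grader_ids, model_id = object$model_id,
    mean_percent = lapply(object$mean_matrices, function(m)
      round(unclass(m) * 100, 2)),
    stress = vapply(object$embeddings, `[[`, 0, "stress"),
    pooled_means = object$pooled_means,
    fraction_model_closer = object$fraction_model_closer,
    p_two_sided = if (is.null(object$permutations)) NULL else
      vapply(object$permutations, `[[`, 0, "p_two_sided"),
    notices = object$notices)
  class(out) <- "summary.trex"
  out
}

#' @export
print.summary.trex <- function(x, ...) {
  cat(sprintf("T-REX summary: %d scans, %d graders%s\n", x$n_scans,
              length(x$grader_ids),
              if (is.null(x$model_id)) "" else " + model"))
  for (sc in names(x$mean_percent)) {
    cat(sprintf("-- scope %s (mean Hamming %%, MDS stress %.2g):\n",
                sc, x$stress[[sc]]))
    print(x$mean_percent[[sc]])
  }
  if (!is.null(x$fraction_model_closer))
    cat(sprintf("fraction of scans with model closer: %.3f\n",
                x$fraction_model_closer))
  if (!is.null(x$p_two_sided))
    cat("permutation p:", paste(sprintf("%s=%.3g", names(x$p_two_sided),
                                        x$p_two_sided), collapse = " "), "\n")
  invisible(x)
}

#' Plot a T-REX analysis
#'
#' @param x A `trex` object.
#' @param type `"mds"` (embedding, default), `"recording"` (per-scan
#'   heatmap), `"heatmap"` (mean-matrix table), or `"boxplot"`.
#' @param scope Scope to plot.
#' @param ... Passed to the underlying plot.
#' @export
plot.trex <- function(x, type = c("mds", "recording", "heatmap", "boxplot"),
                      scope = "all", ...) {
  type <- match.arg(type)
  scope <- check_scope(scope)
  switch(type,
    mds = plot(x$embeddings[[scope]], model_id = x$model_id, ...),
    recording = {
      nr <- neural_recording(x$table, grader_ids = x$grader_ids,
                             model_id = x$model_id)
      draw_recording(nr, ...)
    },
    heatmap = draw_mean_heatmap(x$mean_matrices[[scope]], ...),
    boxplot = {
      vals <- lapply(names(x$boxplots[[scope]]), function(p) {
        ab <- strsplit(p, "-", fixed = TRUE)[[1]]
        pair_rows(x$table, ab[1], ab[2], scope)$distance
      })
      names(vals) <- names(x$boxplots[[scope]])
      graphics::boxplot(vals, ylab = "Hamming distance",
                        main = paste("scope:", scope), las = 2, ...)
    })
  invisible(x)
}

#' Per-scope mean distance tables in percent
#'
#' The heatmap-table view of an analysis: for the overall scope and each
#' compartment, the mean pairwise Hamming distance matrix expressed in
#' percent (two decimals when rendered).
#'
#' @param t A `distance_table`.
#' @param ids Ordered grading ids (default: order of appearance).
#' @param scopes Scopes to include (those present in `t` by default).
#' @return Named list of percent matrices (numeric, not rounded).
#' @export
heatmap_table <- function(t, ids = NULL, scopes = NULL) {
  if (is.null(scopes)) scopes <- intersect(SCOPES, unique(t$scope))
  lapply(stats::setNames(scopes, scopes), function(sc)
    unclass(mean_distance_matrix(t, sc, ids = ids)) * 100)
}

#' Neural-recording grid of per-scan distances
#'
#' The per-scan tabulation of all pairwise overall Hamming distances: one
#' row per grading pair (inter-grader pairs above grader-model pairs), one
#' column per scan. This is the substrate of the neural-recording heatmap,
#' which exposes scan-level structure that mean distances hide.
#'
#' @param t A `distance_table` with overall-scope records.
#' @param grader_ids,model_id Grading ids; grader pairs are ordered first.
#' @param scan_order Scan ordering (default: order of appearance in `t`).
#' @param eye_of_scan Optional named vector mapping scan ids to eye ids;
#'   recorded as an attribute and used to draw separators between eyes.
#' @return A numeric matrix (pairs x scans) with dimnames, class
#'   `neural_recording`, attribute `n_grader_pairs` (rows above the
#'   inter-human / model-versus-human separator) and optionally `eyes`.
#' @export
neural_recording <- function(t, grader_ids, model_id = NULL,
                             scan_order = NULL, eye_of_scan = NULL) {
  if (is.null(scan_order)) scan_order <- unique(t$scan_id)
  gpairs <- utils::combn(grader_ids, 2L, simplify = FALSE)
  mpairs <- if (is.null(model_id)) list() else
    lapply(grader_ids, function(g) c(g, model_id))
  pairs <- c(gpairs, mpairs)
  grid <- matrix(NA_real_, length(pairs), length(scan_order),
                 dimnames = list(vapply(pairs, paste, "", collapse = "-"),
                                 scan_order))
  for (i in seq_along(pairs)) {
    rows <- pair_rows(t, pairs[[i]][1], pairs[[i]][2], "all")
    idx <- match(scan_order, rows$scan_id)
    if (anyNA(idx))
      stop(sprintf("missing overall-scope records for pair (%s, %s)",
                   pairs[[i]][1], pairs[[i]][2]))
    grid[i, ] <- rows$distance[idx]
  }
  structure(grid, n_grader_pairs = length(gpairs),
            eyes = if (is.null(eye_of_scan)) NULL else
              unname(eye_of_scan[scan_order]),
            class = c("neural_recording", "matrix", "array"))
}

recording_palette <- function(n = 256) grDevices::colorRampPalette(
  c("#1a9850", "#fee08b", "#d73027"))(n)

draw_recording <- function(nr, main = "Neural recording", ...) {
  vals <- unclass(nr)
  top <- stats::quantile(vals, 0.99, type = 7)
  if (top <= 0) top <- max(vals, 1e-12)
  z <- pmin(vals, top)
  graphics::image(x = seq_len(ncol(z)), y = seq_len(nrow(z)),
                  z = t(z)[, rev(seq_len(nrow(z))), drop = FALSE],
                  zlim = c(0, top), col = recording_palette(),
                  xlab = "scan", ylab = "", yaxt = "n", main = main, ...)
  graphics::axis(2, at = seq_len(nrow(z)), labels = rev(rownames(z)),
                 las = 2, cex.axis = 0.7)
  ng <- attr(nr, "n_grader_pairs")
  if (ng > 0 && ng < nrow(z))
    graphics::abline(h = nrow(z) - ng + 0.5, lwd = 2)
  eyes <- attr(nr, "eyes")
  if (!is.null(eyes)) {
    sep <- which(eyes[-1] != eyes[-length(eyes)])
    graphics::abline(v = sep + 0.5, lwd = 1)
  }
  invisible(nr)
}

draw_mean_heatmap <- function(m, main = NULL, ...) {
  v <- unclass(m) * 100
  k <- nrow(v)
  graphics::image(seq_len(k), seq_len(k), t(v)[, rev(seq_len(k))],
                  col = recording_palette(), axes = FALSE,
                  xlab = "", ylab = "",
                  main = if (is.null(main))
                    paste("Mean Hamming distance (%), scope", attr(m, "scope"))
                  else main, ...)
  graphics::axis(1, seq_len(k), colnames(v))
  graphics::axis(2, seq_len(k), rev(rownames(v)), las = 2)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k - i + 1, sprintf("%.2f", v[i, j]), cex = 0.9)
  invisible(m)
}

#' Write the full report bundle of an analysis
#'
#' Writes, under `dir`: the distance table CSV, per-scope mean-matrix CSVs
#' (percent, two decimals) with heatmap figures, per-scope embedding CSVs
#' and MDS figures, the neural-recording CSV and figure, per-scope
#' permutation JSONs, and `summary.json` with the headline aggregates.
#' Figures are decoration; the CSV/JSON twins carry the values and are
#' byte-identical across reruns with the same inputs and seed.
#'
#' @param x A `trex` object.
#' @param dir Output directory (created if needed).
#' @param eye_of_scan Optional named scan-to-eye mapping for the recording.
#' @return `dir`, invisibly.
#' @export
write_trex_report <- function(x, dir, eye_of_scan = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_distance_table(x$table, fp("distances.csv"))

  for (sc in x$scopes) {
    m <- x$mean_matrices[[sc]]
    pm <- formatC(unclass(m) * 100, format = "f", digits = 2)
    utils::write.csv(as.data.frame(pm), fp(sprintf("mean_percent_%s.csv", sc)),
                     quote = FALSE)
    grDevices::png(fp(sprintf("heatmap_%s.png", sc)), 640, 640)
    draw_mean_heatmap(m); grDevices::dev.off()
    write_embedding(x$embeddings[[sc]], fp(sprintf("mds_%s.csv", sc)))
    grDevices::png(fp(sprintf("mds_%s.png", sc)), 640, 640)
    plot(x$embeddings[[sc]], model_id = x$model_id)
    grDevices::dev.off()
  }

  if ("all" %in% x$scopes) {
    nr <- neural_recording(x$table, x$grader_ids, x$model_id,
                           eye_of_scan = eye_of_scan)
    utils::write.csv(as.data.frame(unclass(nr)), fp("neural_recording.csv"),
                     quote = FALSE)
    grDevices::png(fp("neural_recording.png"), 1280, 480)
    draw_recording(nr); grDevices::dev.off()
  }

  if (!is.null(x$permutations))
    for (sc in names(x$permutations))
      permutation_result_json(x$permutations[[sc]],
                              fp(sprintf("permutation_%s.json", sc)))

  summary_obj <- list(
    n_scans = length(unique(x$table$scan_id)),
    grader_ids = x$grader_ids, model_id = x$model_id,
    mean_percent = lapply(x$mean_matrices, function(m) {
      v <- round(unclass(m) * 100, 2); dimnames(v) <- dimnames(m)
      as.data.frame(v)
    }),
    pooled_means_percent = if (is.null(x$pooled_means)) NULL else
      lapply(x$pooled_means, function(p)
        list(inter_grader = 100 * p$inter_grader,
             grader_model = 100 * p$grader_model)),
    fraction_model_closer = x$fraction_model_closer,
    p_two_sided = if (is.null(x$permutations)) NULL else
      lapply(x$permutations, `[[`, "p_two_sided"),
    stress = lapply(x$embeddings, `[[`, "stress"),
    seed = x$seed, notices = x$notices)
  jsonlite::write_json(summary_obj, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
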