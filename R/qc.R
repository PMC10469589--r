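# Depth-evenness statistics, rarefaction retention, projected-vs-observed QC.

#' Depth-evenness statistics of a pool
#'
#' Proportions are computed over every library in the pool, but the summary
#' statistics cover only the included libraries — by default the non-blank
#' samples, matching how a study reports its sample read distribution.
#' The coefficient of variation uses the sample (n-1) standard deviation.
#'
#' @param x A [count_table], or a numeric vector of counts/proportions.
#' @param include_blanks Include blanks in the statistics (default `FALSE`;
#'   ignored for plain numeric input).
#' @return Object of class `evenness_stats`: list with `n_included`,
#'   `median_proportion`, `sd_proportion`, `cv` (sd/mean of proportions) and
#'   `median_reads`.
#' @export
evenness_stats <- function(x, include_blanks = FALSE) {
  if (inherits(x, "count_table")) {
    counts <- x$reads_pf
    included <- if (include_blanks) rep(TRUE, nrow(x)) else x$role != "blank"
  } else {
    counts <- as.numeric(x)
    included <- rep(TRUE, length(counts))
  }
  if (sum(included) < 2) {
    stop("evenness statistics need at least 2 included libraries", call. = FALSE)
  }
  p <- counts / sum(counts) # shares of the whole pool, blanks and all
  pi <- p[included]
  structure(list(n_included = sum(included),
                 median_proportion = stats::median(pi),
                 sd_proportion = stats::sd(pi),
                 cv = stats::sd(pi) / mean(pi),
                 median_reads = stats::median(counts[included])),
            class = "evenness_stats")
}

#' @export
print.evenness_stats <- function(x, ...) {
  cat(sprintf(
    "evenness over %d libraries: median proportion %.4g (sd %.4g), CV %.3f, median %s reads\n",
    x$n_included, x$median_proportion, x$sd_proportion, x$cv,
    format(x$median_reads, big.mark = ",")))
  invisible(x)
}

#' Rarefaction retention curve
#'
#' How many libraries survive rarefying to each candidate depth:
#' `retained(d) = #{i : reads_i >= d}`. An even pool keeps nearly all
#' libraries at its median depth; an uneven one sheds them early.
#'
#' @param x A [count_table] or numeric count vector.
#' @param depth_grid Increasing depths to evaluate; default 101 points from 0
#'   to the maximum count, with the median depth added.
#' @param include_blanks Include blanks (default `FALSE` for count tables).
#' @return Object of class `retention_curve`: data.frame with `depth` and
#'   `retained`; attributes `median_depth` and `n`.
#' @export
retention_curve <- function(x, depth_grid = NULL, include_blanks = FALSE) {
  counts <- if (inherits(x, "count_table")) {
    if (include_blanks) x$reads_pf else x$reads_pf[x$role != "blank"]
  } else as.numeric(x)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  med <- stats::median(counts)
  if (is.null(depth_grid)) {
    depth_grid <- sort(unique(c(round(seq(0, max(counts), length.out = 101)), med)))
  } else {
    depth_grid <- sort(unique(as.numeric(depth_grid)))
    if (any(depth_grid < 0)) stop("depth grid must be non-negative", call. = FALSE)
  }
  retained <- vapply(depth_grid, function(d) sum(counts >= d), numeric(1))
  structure(data.frame(depth = depth_grid, retained = retained),
            median_depth = med, n = length(counts),
            class = c("retention_curve", "data.frame"))
}

#' Retention at a given depth
#'
#' @param curve A [retention_curve].
#' @param depth Depth to query (must be on the grid or below/above it).
#' @return Number of libraries with at least `depth` reads.
#' @export
retained_at <- function(curve, depth) {
  stopifnot(inherits(curve, "retention_curve"))
  i <- match(depth, curve$depth)
  if (is.na(i)) stop("depth ", depth, " not on the curve grid", call. = FALSE)
  curve$retained[i]
}

#' Compare projected to observed read counts
#'
#' @param projection A [project_counts()] result (needs `projected_reads`).
#' @param observed A [count_table] over the same libraries.
#' @return Object of class `projection_comparison`: per-library data.frame
#'   (`sample_id`, `projected`, `observed`, `ratio`) with attributes
#'   `rank_correlation` (Spearman) and `mare` (mean absolute relative error,
#'   over libraries with positive projection).
#' @export
compare_projected_observed <- function(projection, observed) {
  stopifnot(inherits(projection, "projection"), inherits(observed, "count_table"))
  if (!"projected_reads" %in% names(projection)) {
    stop("projection lacks counts; call project_counts() first", call. = FALSE)
  }
  if (!setequal(projection$sample_id, observed$sample_id)) {
    stop("projection and observed counts cover different libraries", call. = FALSE)
  }
  obs <- observed$reads_pf[match(projection$sample_id, observed$sample_id)]
  proj <- projection$projected_reads
  tab <- data.frame(sample_id = projection$sample_id, projected = proj,
                    observed = obs, ratio = obs / proj,
                    stringsAsFactors = FALSE)
  pos <- proj > 0
  structure(tab,
            rank_correlation = stats::cor(proj, obs, method = "spearman"),
            mare = mean(abs(obs[pos] - proj[pos]) / proj[pos]),
            class = c("projection_comparison", "data.frame"))
}

#' @export
print.projection_comparison <- function(x, ...) {
  cat(sprintf(
    "projected vs observed over %d libraries: Spearman rho %.3f, MARE %.4f\n",
    nrow(x), attr(x, "rank_correlation"), attr(x, "mare")))
  invisible(x)
}

#' Write a QC report comparing one or two pools
#'
#' @param tables Named list of one or two [count_table]s (e.g.
#'   `list(fluorometric = t1, read_count = t2)`).
#' @param path Output TSV path.
#' @param include_blanks Passed to [evenness_stats()].
#' @return Data frame of per-method statistics, invisibly (also written).
#' @export
write_qc_report <- function(tables, path, include_blanks = FALSE) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("method", seq_along(tables))
  }
  rows <- lapply(names(tables), function(nm) {
    s <- evenness_stats(tables[[nm]], include_blanks = include_blanks)
    data.frame(method = nm, n_included = s$n_included,
               median_proportion = s$median_proportion,
               sd_proportion = s$sd_proportion, cv = s$cv,
               median_reads = s$median_reads, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Plot retention curves with median-depth markers
#'
#' Base-graphics rendition of the rarefaction comparison: one retention
#' curve per pool, dotted vertical line at each pool's median depth.
#'
#' @param x A [retention_curve] or named list of them.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_retention <- function(x, ...) {
  curves <- if (inherits(x, "retention_curve")) list(pool = x) else x
  cols <- grDevices::hcl.colors(max(2, length(curves)), "Dark 2")
  xmax <- max(vapply(curves, function(cv) max(cv$depth), numeric(1)))
  ymax <- max(vapply(curves, function(cv) max(cv$retained), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "rarefaction depth (read pairs)",
                 ylab = "libraries retained", ...)
  for (k in seq_along(curves)) {
    graphics::lines(curves[[k]]$depth, curves[[k]]$retained, col = cols[k],
                    type = "s", lwd = 2)
    graphics::abline(v = attr(curves[[k]], "median_depth"), col = cols[k],
                     lty = 3)
  }
  graphics::legend("bottomleft", legend = names(curves), col = cols[seq_along(curves)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' @export
plot.retention_curve <- function(x, ...) plot_retention(x, ...)
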