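# Core method: read-share index, re-pooling volumes, projected representation.
#
# The pooling model: a library's read share in a run is proportional to the
# moles of sequencing-competent molecules it contributed. If library i
# contributed prior_volume_i nL to the first pool and captured share p_i of
# its reads, its reads-per-nL rate is p_i / prior_volume_i; choosing a new
# volume v_i moves its expected share to v_i * p_i / prior_volume_i (up to
# the common normalizing constant). Equal representation therefore wants
# v_i proportional to prior_volume_i / p_i, bounded by what the dispenser
# can transfer.

#' Compute the per-library read-share index
#'
#' Each library's share of the pool: `p_i = c_i / sum(c)`, where `c` is
#' `reads_pf` in `"reads"` mode or `feature_count` (reads on target) in
#' `"features"` mode. Normalizing on feature counts equalizes usable data
#' rather than raw depth.
#'
#' @param counts A [count_table].
#' @param mode `"reads"` or `"features"`.
#' @return Object of class `reads_index`: data.frame with `sample_id`,
#'   `role`, `proportion`; attribute `mode`. Proportions sum to one over all
#'   libraries in the pool.
#' @export
compute_reads_index <- function(counts, mode = c("reads", "features")) {
  stopifnot(inherits(counts, "count_table"))
  mode <- match.arg(mode)
  if (mode == "features") {
    if (!"feature_count" %in% names(counts) || anyNA(counts$feature_count)) {
      stop("features mode requires a complete feature_count column", call. = FALSE)
    }
    c_i <- counts$feature_count
  } else {
    c_i <- counts$reads_pf
  }
  tot <- sum(c_i)
  if (tot <= 0) {
    stop("degenerate input: all ", mode, " counts are zero", call. = FALSE)
  }
  structure(
    data.frame(sample_id = counts$sample_id, role = counts$role,
               proportion = c_i / tot, stringsAsFactors = FALSE),
    mode = mode, class = c("reads_index", "data.frame"))
}

#' Normalization configuration
#'
#' Volume bounds default to the 10--1000 nL transfer range of the workflow;
#' the 2.5 nL quantum is the droplet increment of the Echo 550 acoustic
#' dispenser, so every emitted volume is a transferable multiple.
#'
#' @param v_min_nl Minimum transfer volume (nL).
#' @param v_max_nl Maximum transfer volume (nL).
#' @param quantum_nl Droplet increment (nL); must divide both bounds exactly.
#' @param blank_policy `"fixed_min"` pools every blank at `v_min_nl`
#'   (blanks carry few reads by design; boosting them to parity would waste
#'   depth); `"as_sample"` treats blanks like samples.
#' @param zero_count_policy What to do with libraries whose index is zero:
#'   `"max_volume_flagged"` assigns `v_max_nl` and flags them (conservative,
#'   visible); `"exclude_flagged"` drops them from the pool with a flag.
#' @param transfer_cap_nl Optional per-transfer cap; picklist rows above it
#'   are split (NA = no cap).
#' @return Object of class `normalization_config` (a list).
#' @export
normalization_config <- function(v_min_nl = 10, v_max_nl = 1000,
                                 quantum_nl = 2.5,
                                 blank_policy = c("fixed_min", "as_sample"),
                                 zero_count_policy = c("max_volume_flagged",
                                                       "exclude_flagged"),
                                 transfer_cap_nl = NA_real_) {
  blank_policy <- match.arg(blank_policy)
  zero_count_policy <- match.arg(zero_count_policy)
  stopifnot(v_min_nl > 0, v_max_nl >= v_min_nl, quantum_nl > 0)
  if (!is_quantum_multiple(v_min_nl, quantum_nl) ||
      !is_quantum_multiple(v_max_nl, quantum_nl)) {
    stop("quantum_nl must divide v_min_nl and v_max_nl exactly", call. = FALSE)
  }
  structure(list(v_min_nl = v_min_nl, v_max_nl = v_max_nl,
                 quantum_nl = quantum_nl, blank_policy = blank_policy,
                 zero_count_policy = zero_count_policy,
                 transfer_cap_nl = transfer_cap_nl),
            class = "normalization_config")
}

is_quantum_multiple <- function(v, quantum, tol = 1e-6) {
  abs(v / quantum - round(v / quantum)) < tol
}

# Nearest multiple of quantum, round half up.
quantize_volume <- function(v, quantum) {
  floor(v / quantum + 0.5) * quantum
}

#' Compute re-pooling volumes from a read-share index
#'
#' The transfer volume that equalizes representation is proportional to
#' `prior_volume_i / p_i`. Volumes are scaled so the most underrepresented
#' sample library receives exactly `v_max_nl` ("max fill": use the whole
#' dynamic range of the dispenser), clamped to
#' `[v_min_nl, v_max_nl]`, and quantized to the droplet increment (nearest
#' multiple, half up). Blanks and zero-count libraries are handled by the
#' configured policies and flagged, never silently altered.
#'
#' @param index A [compute_reads_index()] result.
#' @param prior_volumes Per-library volumes in the prior pool (nL); default
#'   all equal (an equimolar-intent first pool).
#' @param roles Per-library roles; default taken from the index.
#' @param config A [normalization_config()].
#' @return Object of class `volume_assignment`: data.frame with `sample_id`,
#'   `role`, `proportion`, `prior_volume_nl`, `volume_nl`, `raw_volume_nl`
#'   (clamped but not yet quantized, for diagnostics), `flags`
#'   (comma-separated subset of `clamped_low`, `clamped_high`, `zero_count`,
#'   `blank_fixed`, `excluded`); the config is attached as an attribute.
#' @export
compute_volumes <- function(index, prior_volumes = NULL, roles = NULL,
                            config = normalization_config()) {
  stopifnot(inherits(index, "reads_index"), inherits(config, "normalization_config"))
  n <- nrow(index)
  p <- index$proportion
  if (is.null(roles)) roles <- index$role
  if (is.null(prior_volumes)) prior_volumes <- rep(1, n)
  prior_volumes <- rep_len(as.numeric(prior_volumes), n)
  if (anyNA(prior_volumes)) prior_volumes[is.na(prior_volumes)] <- 1
  if (any(prior_volumes <= 0)) stop("prior volumes must be positive", call. = FALSE)

  blank_fixed <- roles == "blank" & config$blank_policy == "fixed_min"
  zero <- p <= 0
  # libraries whose volume comes from the index (not fixed by policy)
  indexed <- !blank_fixed & !zero
  if (!any(indexed)) {
    stop("no library with a positive index to normalize", call. = FALSE)
  }

  u <- rep(NA_real_, n)
  u[indexed] <- prior_volumes[indexed] / p[indexed]
  # max-fill anchor: the neediest non-blank library gets exactly v_max, so
  # blanks kept "as_sample" cannot compress the samples' dynamic range
  anchor <- indexed & roles != "blank"
  if (!any(anchor)) anchor <- indexed
  scale <- config$v_max_nl / max(u[anchor])
  u <- u * scale

  vol <- rep(NA_real_, n)
  raw <- rep(NA_real_, n)
  flags <- vector("list", n)
  clamped_low <- indexed & u < config$v_min_nl
  clamped_high <- indexed & u > config$v_max_nl + 1e-9
  raw[indexed] <- pmin(pmax(u[indexed], config$v_min_nl), config$v_max_nl)
  vol[indexed] <- quantize_volume(raw[indexed], config$quantum_nl)
  # quantization can step past a bound; pull back inside
  vol[indexed] <- pmin(pmax(vol[indexed], config$v_min_nl), config$v_max_nl)

  vol[blank_fixed] <- config$v_min_nl
  excluded <- rep(FALSE, n)
  if (any(zero)) {
    if (config$zero_count_policy == "max_volume_flagged") {
      vol[zero] <- config$v_max_nl
    } else {
      vol[zero] <- 0
      excluded <- zero
    }
  }
  vol[zero & blank_fixed] <- config$v_min_nl # blank policy wins for blanks
  raw[!indexed] <- vol[!indexed]

  for (i in seq_len(n)) {
    f <- character(0)
    if (clamped_low[i]) f <- c(f, "clamped_low")
    if (clamped_high[i]) f <- c(f, "clamped_high")
    if (zero[i] && !blank_fixed[i]) f <- c(f, "zero_count")
    if (blank_fixed[i]) f <- c(f, "blank_fixed")
    if (excluded[i]) f <- c(f, "excluded")
    flags[[i]] <- f
  }

  structure(
    data.frame(sample_id = index$sample_id, role = roles,
               proportion = p, prior_volume_nl = prior_volumes,
               volume_nl = vol, raw_volume_nl = raw,
               flags = vapply(flags, paste, "", collapse = ","),
               stringsAsFactors = FALSE),
    config = config, mode = attr(index, "mode"),
    class = c("volume_assignment", "data.frame"))
}

#' Test volume-assignment flags
#'
#' @param x A `volume_assignment`.
#' @param flag Flag name, e.g. `"clamped_low"`.
#' @return Logical vector over libraries.
#' @export
has_flag <- function(x, flag) {
  stopifnot(inherits(x, "volume_assignment"))
  vapply(strsplit(x$flags, ",", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Project post-normalization read proportions
#'
#' Each library's first-run reads-per-volume rate is `m_i = p_i /
#' prior_volume_i`; after re-pooling at the assigned volumes the expected
#' read share is `p'_i = v_i * m_i / sum(v_j * m_j)`. Libraries excluded from
#' the pool (volume 0) project to zero.
#'
#' @param volumes A [compute_volumes()] result.
#' @param index The [compute_reads_index()] the volumes were derived from.
#' @param prior_volumes Prior pool volumes; default those stored in `volumes`.
#' @return Object of class `projection`: data.frame with `sample_id`, `role`,
#'   `projected_proportion` (sums to one over pooled libraries).
#' @export
project_proportions <- function(volumes, index, prior_volumes = NULL) {
  stopifnot(inherits(volumes, "volume_assignment"), inherits(index, "reads_index"))
  if (!identical(volumes$sample_id, index$sample_id)) {
    stop("volumes and index cover different libraries", call. = FALSE)
  }
  if (is.null(prior_volumes)) prior_volumes <- volumes$prior_volume_nl
  m <- index$proportion / prior_volumes
  w <- volumes$volume_nl * m
  if (sum(w) <= 0) stop("projected pool is empty", call. = FALSE)
  structure(
    data.frame(sample_id = volumes$sample_id, role = volumes$role,
               projected_proportion = w / sum(w), stringsAsFactors = FALSE),
    class = c("projection", "data.frame"))
}

#' Project read counts at a stated depth
#'
#' @param projection A [project_proportions()] result.
#' @param depth Total sequencing depth (read pairs) to project to.
#' @param on_target_fraction Optional per-library fraction of reads on
#'   target (`feature_count / reads_pf`), each in \[0, 1\]; adds a projected
#'   on-target count column.
#' @return The projection with `projected_reads` (and, when fractions are
#'   given, `projected_on_target`) columns added.
#' @export
project_counts <- function(projection, depth, on_target_fraction = NULL) {
  stopifnot(inherits(projection, "projection"), depth > 0)
  projection$projected_reads <- projection$projected_proportion * depth
  if (!is.null(on_target_fraction)) {
    f <- rep_len(as.numeric(on_target_fraction), nrow(projection))
    if (any(f < 0 | f > 1, na.rm = TRUE)) {
      stop("on-target fractions must lie in [0, 1]", call. = FALSE)
    }
    projection$projected_on_target <- projection$projected_reads * f
  }
  projection
}

#' Write the per-library volume/projection report
#'
#' @param volumes A `volume_assignment`.
#' @param path Output TSV path.
#' @param projection Optional matching `projection` (adds projected columns).
#' @param counts Optional joined [count_table] (adds well and reads columns).
#' @param depth Optional depth for projected read counts.
#' @return `path`, invisibly.
#' @export
write_volume_report <- function(volumes, path, projection = NULL,
                                counts = NULL, depth = NULL) {
  stopifnot(inherits(volumes, "volume_assignment"))
  out <- data.frame(sample_id = volumes$sample_id, stringsAsFactors = FALSE)
  if (!is.null(counts)) {
    i <- match(out$sample_id, counts$sample_id)
    if ("well" %in% names(counts)) out$well <- counts$well[i]
    out$reads_pf <- counts$reads_pf[i]
  }
  out$role <- volumes$role
  out$proportion <- volumes$proportion
  out$volume_nl <- volumes$volume_nl
  out$flags <- volumes$flags
  if (!is.null(projection)) {
    out$projected_proportion <- projection$projected_proportion
    if (!is.null(depth)) out$projected_reads <- projection$projected_proportion * depth
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.volume_assignment <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("volume_assignment: %d libraries, volumes %g-%g nL (quantum %g)\n",
              nrow(x), min(x$volume_nl[x$volume_nl > 0]), max(x$volume_nl),
              cfg$quantum_nl))
  cat(sprintf("  clamped low %d, clamped high %d, zero-count %d, blanks fixed %d\n",
              sum(has_flag(x, "clamped_low")), sum(has_flag(x, "clamped_high")),
              sum(has_flag(x, "zero_count")), sum(has_flag(x, "blank_fixed"))))
  invisible(x)
}

#' @export
summary.volume_assignment <- function(object, ...) {
  print(object)
  cat("volume distribution (nL):\n")
  print(summary(object$volume_nl))
  invisible(object)
}
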