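# Per-library count tables and FASTQ read-pair counting.

#' Construct a per-library count table
#'
#' Holds reads passing filter (read pairs) per library, optionally the number
#' of reads on target ("feature counts", e.g. non-ribosomal reads in
#' metatranscriptomics), the volume each library contributed to the prior
#' pool, and the library role.
#'
#' @param sample_id Unique library identifiers.
#' @param reads_pf Non-negative integer read-pair counts passing filter.
#' @param feature_count Optional non-negative on-target counts,
#'   `feature_count <= reads_pf` element-wise.
#' @param prior_volume_nl Optional positive prior pool volumes (nL).
#' @param role Optional `"sample"`/`"blank"`; defaults to `"sample"`.
#' @param well Optional well labels (attached by [join_counts_to_plate()]).
#' @return Object of class `count_table`: a data.frame with attribute
#'   `total_depth` equal to `sum(reads_pf)`.
#' @export
count_table <- function(sample_id, reads_pf, feature_count = NULL,
                        prior_volume_nl = NULL, role = NULL, well = NULL) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (n == 0) stop("count table needs at least one record", call. = FALSE)
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in count table: ",
         paste(sQuote(unique(dup)), collapse = ", "), call. = FALSE)
  }
  reads_pf <- as.numeric(reads_pf)
  if (anyNA(reads_pf) || any(reads_pf < 0) || any(reads_pf != floor(reads_pf))) {
    stop("reads_pf must be non-negative integers", call. = FALSE)
  }
  if (!is.null(feature_count)) {
    feature_count <- as.numeric(feature_count)
    chk <- !is.na(feature_count)
    if (any(feature_count[chk] < 0) || any(feature_count[chk] != floor(feature_count[chk]))) {
      stop("feature_count must be non-negative integers", call. = FALSE)
    }
    over <- chk & feature_count > reads_pf
    if (any(over)) {
      stop("feature_count exceeds reads_pf for: ",
           paste(sQuote(sample_id[over]), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(prior_volume_nl)) {
    prior_volume_nl <- as.numeric(prior_volume_nl)
    chk <- !is.na(prior_volume_nl)
    if (any(prior_volume_nl[chk] <= 0)) {
      stop("prior_volume_nl must be positive", call. = FALSE)
    }
  }
  if (is.null(role)) role <- rep("sample", n)
  role <- tolower(as.character(role))
  role[is.na(role) | !nzchar(role)] <- "sample"
  if (any(!role %in% c("sample", "blank"))) {
    stop("role must be 'sample' or 'blank'", call. = FALSE)
  }
  df <- data.frame(sample_id = sample_id, reads_pf = reads_pf,
                   stringsAsFactors = FALSE)
  if (!is.null(feature_count)) df$feature_count <- feature_count
  if (!is.null(prior_volume_nl)) df$prior_volume_nl <- prior_volume_nl
  df$role <- rep_len(role, n)
  if (!is.null(well)) df$well <- as.character(well)
  rownames(df) <- NULL
  structure(df, total_depth = sum(reads_pf),
            class = c("count_table", "data.frame"))
}

#' Total sequencing depth of a count table
#'
#' @param x A [count_table].
#' @return Sum of `reads_pf` (read pairs).
#' @export
total_depth <- function(x) {
  stopifnot(inherits(x, "count_table"))
  sum(x$reads_pf)
}

#' Read a count table from TSV/CSV
#'
#' The delimiter is taken from the extension: `.tsv` is tab-separated,
#' anything else comma-separated. Mandatory columns `sample_id` and
#' `reads_pf`; optional `feature_count`, `prior_volume_nl`, `role`, `well`.
#'
#' @param path Input path.
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  sep <- if (grepl("\\.tsv(\\.gz)?$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("sample_id", "reads_pf"), names(df))
  if (length(miss)) {
    stop("count table ", sQuote(path), " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pick <- function(col) if (col %in% names(df)) df[[col]] else NULL
  count_table(df$sample_id, df$reads_pf,
              feature_count = pick("feature_count"),
              prior_volume_nl = pick("prior_volume_nl"),
              role = pick("role"), well = pick("well"))
}

#' Write a count table to TSV/CSV
#'
#' @param x A [count_table].
#' @param path Output path; `.tsv` writes tabs, otherwise commas.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Count read pairs in FASTQ files
#'
#' Streams one or two FASTQ(.gz) files and returns the number of read
#' *pairs*: with `r1` and `r2` the R1 record count is returned after checking
#' that R2 has the same number of records; with a single file its record
#' count is returned (single-end reads count as pairs of multiplicity one).
#'
#' @param r1 Path to the (first) FASTQ file, plain or gzip.
#' @param r2 Optional path to the mate file.
#' @return Non-negative integer number of read pairs.
#' @export
count_fastq_reads <- function(r1, r2 = NULL) {
  n1 <- fastq_record_count(r1)
  if (!is.null(r2)) {
    n2 <- fastq_record_count(r2)
    if (n1 != n2) {
      stop("R1/R2 record count mismatch: ", n1, " vs ", n2, " (",
           sQuote(r1), ", ", sQuote(r2), ")", call. = FALSE)
    }
  }
  n1
}

# Streaming 4-line-record counter with structure validation; reports the
# index of the offending record on truncation or malformed headers.
fastq_record_count <- function(path, chunk_lines = 40000L) {
  con <- gzfile(path, open = "rt") # gzfile transparently reads plain text too
  on.exit(close(con))
  n <- 0L
  carry <- character(0)
  repeat {
    lines <- readLines(con, n = chunk_lines, warn = FALSE)
    if (length(lines) == 0 && length(carry) == 0) break
    lines <- c(carry, lines)
    nfull <- (length(lines) %/% 4L) * 4L
    if (nfull > 0L) {
      heads <- lines[seq.int(1L, nfull, by = 4L)]
      plus <- lines[seq.int(3L, nfull, by = 4L)]
      bad <- !startsWith(heads, "@")
      if (any(bad)) {
        stop("malformed FASTQ record ", n + which(bad)[1], " in ", sQuote(path),
             ": header does not start with '@'", call. = FALSE)
      }
      bad <- !startsWith(plus, "+")
      if (any(bad)) {
        stop("malformed FASTQ record ", n + which(bad)[1], " in ", sQuote(path),
             ": separator line does not start with '+'", call. = FALSE)
      }
      n <- n + nfull %/% 4L
    }
    carry <- if (nfull < length(lines)) lines[(nfull + 1L):length(lines)] else character(0)
    if (length(lines) < chunk_lines) {
      if (length(carry)) {
        stop("truncated FASTQ record ", n + 1L, " in ", sQuote(path),
             ": ", length(carry), " trailing line(s)", call. = FALSE)
      }
      break
    }
  }
  n
}

#' Join a count table to a plate map
#'
#' Resolves each library's well and role from the plate map (the plate map's
#' role wins). The join is outer on the plate side: plate wells with no
#' counts become zero-read libraries flagged `missing = TRUE`, so no library
#' silently drops out of the pool. Counts with no plate record are an error.
#'
#' @param counts A [count_table].
#' @param plate A [plate_map].
#' @return A [count_table] with `well`, `role` and logical `missing` columns,
#'   one row per plate record, in plate (row-major well) order.
#' @export
join_counts_to_plate <- function(counts, plate) {
  stopifnot(inherits(counts, "count_table"), inherits(plate, "plate_map"))
  orphan <- setdiff(counts$sample_id, plate$sample_id)
  if (length(orphan)) {
    stop("sample(s) in counts but not in plate map: ",
         paste(sQuote(orphan), collapse = ", "), call. = FALSE)
  }
  idx <- match(plate$sample_id, counts$sample_id)
  missing <- is.na(idx)
  get <- function(col, default) {
    if (col %in% names(counts)) {
      v <- counts[[col]][idx]
      v[missing] <- default
      v
    } else NULL
  }
  reads <- counts$reads_pf[idx]
  reads[missing] <- 0
  out <- count_table(sample_id = plate$sample_id, reads_pf = reads,
                     feature_count = get("feature_count", 0),
                     prior_volume_nl = get("prior_volume_nl", NA_real_),
                     role = plate$role, well = plate$well)
  out$missing <- missing
  out
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d libraries (%d blanks), total depth %s read pairs\n",
              nrow(x), sum(x$role == "blank"),
              format(total_depth(x), big.mark = ",")))
  if ("feature_count" %in% names(x)) {
    cat(sprintf("  on-target counts present (total %s)\n",
                format(sum(x$feature_count, na.rm = TRUE), big.mark = ",")))
  }
  invisible(x)
}
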