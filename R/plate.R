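# 384-well plate model: well addresses, plate maps, sample roles.

PLATE_ROWS <- LETTERS[1:16] # A..P
PLATE_COLS <- 1:24

#' Parse a well label into a canonical well address
#'
#' Well addresses on a 384-well plate are a row letter `A`--`P` followed by a
#' column number `1`--`24`. Zero-padded input (`"A01"`) is accepted; the
#' canonical form has no padding (`"A1"`).
#'
#' @param x Character vector of well labels.
#' @return A data.frame with columns `row` (letter) and `column` (integer),
#'   one row per input label.
#' @examples
#' parse_well(c("A1", "p24", "B07"))
#' @export
parse_well <- function(x) {
  if (length(x) == 0) stop("no well labels supplied", call. = FALSE)
  x0 <- toupper(trimws(as.character(x)))
  bad <- is.na(x0) | !grepl("^[A-Z][0-9]{1,2}$", x0)
  if (any(bad)) {
    stop("malformed well label(s): ",
         paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
  }
  row <- substr(x0, 1, 1)
  col <- as.integer(substr(x0, 2, nchar(x0)))
  if (any(!row %in% PLATE_ROWS)) {
    off <- unique(x[!row %in% PLATE_ROWS])
    stop("well row out of range A-P: ", paste(sQuote(off), collapse = ", "),
         call. = FALSE)
  }
  if (any(col < 1L | col > 24L)) {
    off <- unique(x[col < 1L | col > 24L])
    stop("well column out of range 1-24: ", paste(sQuote(off), collapse = ", "),
         call. = FALSE)
  }
  data.frame(row = row, column = col, stringsAsFactors = FALSE)
}

#' Format well addresses canonically
#'
#' @param row Row letters (`A`--`P`).
#' @param column Column numbers (1--24).
#' @return Character vector of canonical labels (`"A1"`, `"P24"`).
#' @export
format_well <- function(row, column) {
  stopifnot(all(row %in% PLATE_ROWS), all(column %in% PLATE_COLS))
  paste0(row, as.integer(column))
}

#' All 384 well labels in row-major order
#'
#' Row-major means A1, A2, ..., A24, B1, ..., P24 — the iteration and output
#' order used throughout the package.
#'
#' @return Character vector of length 384.
#' @export
all_wells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

# Integer sort key for row-major well order.
well_order_key <- function(well) {
  w <- parse_well(well)
  (match(w$row, PLATE_ROWS) - 1L) * 24L + w$column
}

#' Construct a plate map
#'
#' A plate map associates each library (sample or extraction blank) with a
#' source plate and well. The reference study design is 352 samples plus 32
#' negative-control extraction blanks on one 384-well plate.
#'
#' @param sample_id Unique library identifiers.
#' @param well Well labels (canonicalized via [parse_well()]).
#' @param role `"sample"` or `"blank"`; defaults to all `"sample"`.
#' @param source_plate Source plate name(s); recycled.
#' @param plate_id Identifier for the map as a whole.
#' @param blank_prefix Case-insensitive `sample_id` prefix that marks blanks
#'   when `role` is not given explicitly.
#' @return An object of class `plate_map`: a data.frame with columns
#'   `sample_id`, `well`, `role`, `source_plate`, rows in row-major well order.
#' @export
plate_map <- function(sample_id, well, role = NULL, source_plate = "Plate1",
                      plate_id = "plate", blank_prefix = "BLANK") {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (n == 0) stop("plate map needs at least one record", call. = FALSE)
  if (n > 384) stop("plate map has ", n, " records; a 384-well plate holds at most 384",
                    call. = FALSE)
  if (any(!nzchar(sample_id)) || anyNA(sample_id)) {
    stop("empty or missing sample_id in plate map", call. = FALSE)
  }
  wp <- parse_well(well)
  well <- format_well(wp$row, wp$column)
  source_plate <- rep_len(as.character(source_plate), n)
  if (is.null(role)) {
    role <- ifelse(startsWith(toupper(sample_id), toupper(blank_prefix)),
                   "blank", "sample")
  } else {
    role <- tolower(as.character(role))
    role[is.na(role) | !nzchar(role)] <- "sample"
  }
  if (any(!role %in% c("sample", "blank"))) {
    stop("role must be 'sample' or 'blank'; got: ",
         paste(sQuote(unique(role[!role %in% c("sample", "blank")])), collapse = ", "),
         call. = FALSE)
  }
  dup_id <- sample_id[duplicated(sample_id)]
  if (length(dup_id)) {
    stop("duplicate sample_id in plate map: ",
         paste(sQuote(unique(dup_id)), collapse = ", "), call. = FALSE)
  }
  key <- paste(source_plate, well, sep = "/")
  dup_w <- key[duplicated(key)]
  if (length(dup_w)) {
    stop("duplicate well in plate map: ",
         paste(sQuote(unique(dup_w)), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(sample_id = sample_id, well = well, role = role,
                   source_plate = source_plate, stringsAsFactors = FALSE)
  df <- df[order(df$source_plate, well_order_key(df$well)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, plate_id = plate_id, class = c("plate_map", "data.frame"))
}

#' Read a plate map from CSV
#'
#' The file must have a header with at least `sample_id` and `well` columns;
#' `role` and `source_plate` are optional. Without a `role` column, blanks are
#' recognized by a case-insensitive `sample_id` prefix (default `"BLANK"`).
#'
#' @param path Path to a CSV plate map.
#' @inheritParams plate_map
#' @return A [plate_map] object.
#' @export
read_plate_map <- function(path, plate_id = basename(path), blank_prefix = "BLANK") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "well")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("plate map ", sQuote(path), " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  plate_map(sample_id = df$sample_id, well = df$well,
            role = if ("role" %in% names(df)) df$role else NULL,
            source_plate = if ("source_plate" %in% names(df)) df$source_plate else "Plate1",
            plate_id = plate_id, blank_prefix = blank_prefix)
}

#' Write a plate map to canonical CSV
#'
#' Canonical form: header `sample_id,well,role,source_plate`, rows in
#' row-major well order, unpadded well labels. Reading a canonical file and
#' writing it back is byte-identical.
#'
#' @param x A [plate_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_map <- function(x, path) {
  stopifnot(inherits(x, "plate_map"))
  utils::write.csv(as.data.frame(x)[, c("sample_id", "well", "role", "source_plate")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.plate_map <- function(x, ...) {
  tab <- table(factor(x$role, levels = c("sample", "blank")))
  cat(sprintf("plate_map '%s': %d libraries (%d samples, %d blanks) on %d plate(s)\n",
              attr(x, "plate_id"), nrow(x), tab[["sample"]], tab[["blank"]],
              length(unique(x$source_plate))))
  invisible(x)
}
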