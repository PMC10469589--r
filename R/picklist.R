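# Echo cherry-pick picklist generation and round-trip reading.

ECHO_HEADER <- c("Source Plate Name", "Source Well", "Destination Plate Name",
                 "Destination Well", "Transfer Volume")

#' Build an acoustic-dispenser picklist from volume assignments
#'
#' One transfer row per pooled library, in row-major source-well order.
#' Libraries excluded by policy (volume 0) are omitted. Volumes above the
#' configured per-transfer cap are split into consecutive rows whose volumes
#' sum exactly to the assignment.
#'
#' @param volumes A [compute_volumes()] result.
#' @param plate A [plate_map] resolving each library's source plate/well.
#' @param destination_plate Destination plate name.
#' @param destination_well Destination well label (the pool).
#' @return Object of class `picklist`: data.frame with Echo cherry-pick
#'   columns `source_plate`, `source_well`, `destination_plate`,
#'   `destination_well`, `transfer_volume_nl`, plus `sample_id`.
#' @export
build_picklist <- function(volumes, plate, destination_plate = "POOL",
                           destination_well = "A1") {
  stopifnot(inherits(volumes, "volume_assignment"), inherits(plate, "plate_map"))
  cfg <- attr(volumes, "config")
  keep <- volumes$volume_nl > 0
  ids <- volumes$sample_id[keep]
  miss <- setdiff(ids, plate$sample_id)
  if (length(miss)) {
    stop("no source well for library(ies): ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  i <- match(ids, plate$sample_id)
  dw <- parse_well(destination_well)
  rows <- data.frame(sample_id = ids,
                     source_plate = plate$source_plate[i],
                     source_well = plate$well[i],
                     destination_plate = destination_plate,
                     destination_well = format_well(dw$row, dw$column),
                     transfer_volume_nl = volumes$volume_nl[keep],
                     stringsAsFactors = FALSE)
  rows <- rows[order(rows$source_plate, well_order_key(rows$source_well)), ,
               drop = FALSE]
  cap <- cfg$transfer_cap_nl
  if (!is.na(cap)) {
    if (!is_quantum_multiple(cap, cfg$quantum_nl)) {
      stop("transfer cap must be a multiple of the quantum", call. = FALSE)
    }
    rows <- split_transfers(rows, cap)
  }
  rownames(rows) <- NULL
  structure(rows, quantum_nl = cfg$quantum_nl,
            class = c("picklist", "data.frame"))
}

# Split rows whose volume exceeds the per-transfer cap into full-cap rows
# plus a remainder; volumes sum exactly (all quantized arithmetic).
split_transfers <- function(rows, cap) {
  out <- lapply(seq_len(nrow(rows)), function(k) {
    v <- rows$transfer_volume_nl[k]
    if (v <= cap) return(rows[k, , drop = FALSE])
    nfull <- floor((v - 1e-9) / cap)
    parts <- c(rep(cap, nfull), v - nfull * cap)
    parts <- parts[parts > 0]
    rep_rows <- rows[rep(k, length(parts)), , drop = FALSE]
    rep_rows$transfer_volume_nl <- parts
    rep_rows
  })
  do.call(rbind, out)
}

# Volumes printed without trailing zeros beyond one decimal: "142.5", "1000".
format_echo_volume <- function(v) {
  ifelse(abs(v - round(v)) < 1e-9,
         formatC(round(v), format = "d"),
         formatC(v, format = "f", digits = 1))
}

#' Write a picklist as Echo cherry-pick CSV
#'
#' Header `Source Plate Name,Source Well,Destination Plate Name,Destination
#' Well,Transfer Volume`, volumes in nL.
#'
#' @param x A [picklist].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_picklist <- function(x, path) {
  stopifnot(inherits(x, "picklist"))
  lines <- c(paste(ECHO_HEADER, collapse = ","),
             paste(x$source_plate, x$source_well, x$destination_plate,
                   x$destination_well, format_echo_volume(x$transfer_volume_nl),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read an Echo cherry-pick CSV
#'
#' @param path Input path.
#' @param quantum_nl Droplet increment every volume must be a multiple of.
#' @return A [picklist] (without `sample_id`, which the Echo format does not
#'   carry).
#' @export
read_picklist <- function(path, quantum_nl = 2.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(ECHO_HEADER, names(df))
  if (length(miss)) {
    stop("picklist ", sQuote(path), " lacks column(s): ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(structure(
      data.frame(source_plate = character(0), source_well = character(0),
                 destination_plate = character(0),
                 destination_well = character(0),
                 transfer_volume_nl = numeric(0), stringsAsFactors = FALSE),
      quantum_nl = quantum_nl, class = c("picklist", "data.frame")))
  }
  v <- as.numeric(df[["Transfer Volume"]])
  if (anyNA(v) || any(v <= 0)) {
    stop("picklist volumes must be positive numbers", call. = FALSE)
  }
  bad <- !is_quantum_multiple(v, quantum_nl)
  if (any(bad)) {
    stop("picklist volume(s) not a multiple of ", quantum_nl, " nL: ",
         paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  }
  sw <- parse_well(df[["Source Well"]])
  dw <- parse_well(df[["Destination Well"]])
  structure(
    data.frame(source_plate = df[["Source Plate Name"]],
               source_well = format_well(sw$row, sw$column),
               destination_plate = df[["Destination Plate Name"]],
               destination_well = format_well(dw$row, dw$column),
               transfer_volume_nl = v, stringsAsFactors = FALSE),
    quantum_nl = quantum_nl, class = c("picklist", "data.frame"))
}

#' @export
print.picklist <- function(x, ...) {
  cat(sprintf("picklist: %d transfers, %g nL total, %d source plate(s) -> %s\n",
              nrow(x), sum(x$transfer_volume_nl),
              length(unique(x$source_plate)),
              paste(unique(paste0(x$destination_plate, "/", x$destination_well)),
                    collapse = ", ")))
  invisible(x)
}
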