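#' Read a SAM alignment file into a tibble of alignment records
#'
#' Parses SAM text (header optional, 11 mandatory columns per alignment line)
#' into one row per alignment. SAM 1-based leftmost positions are converted to
#' 0-based half-open intervals; the interval end is derived from the CIGAR
#' reference-consuming operations (M/D/N/=/X). Flag bit 0x4 marks the record
#' unmapped (no coordinates retained) and 0x200 marks a QC failure.
#'
#' The number of reported placements per read (`hit_count`) is taken from the
#' NH tag when present; otherwise it is inferred as the number of mapped
#' alignment lines sharing the read id, so inference is independent of the
#' order of lines in the file.
#'
#' @param path Path to a SAM text file.
#' @return A tibble with columns `read_id`, `reference`, `start`, `end`
#'   (0-based half-open; `NA` when unmapped), `mapped`, `mapq`, `hit_count`,
#'   `qc_fail`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) {
    stop_countnet(sprintf("SAM file not found: %s", path),
                  class = "countnet_io_error")
  }
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  refs <- character()
  sq <- lines[is_header & startsWith(lines, "@SQ")]
  if (length(sq)) {
    refs <- stringr::str_match(sq, "SN:([^\t]+)")[, 2]
    refs <- refs[!is.na(refs)]
  }
  body_idx <- which(!is_header & nzchar(lines))
  if (!length(body_idx)) {
    return(tibble::tibble(
      read_id = character(), reference = character(),
      start = integer(), end = integer(), mapped = logical(),
      mapq = integer(), hit_count = integer(), qc_fail = logical()
    ))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) {
    bad <- body_idx[which(nf < 11)[1]]
    stop_countnet(
      sprintf("malformed SAM line %d: expected >= 11 tab-separated fields, got %d",
              bad, nf[which(nf < 11)[1]]),
      class = "countnet_format_error"
    )
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- suppressWarnings(as.integer(get(2)))
  pos <- suppressWarnings(as.integer(get(4)))
  if (anyNA(flag) || anyNA(pos)) {
    bad <- body_idx[which(is.na(flag) | is.na(pos))[1]]
    stop_countnet(
      sprintf("malformed SAM line %d: FLAG and POS must be integers", bad),
      class = "countnet_format_error"
    )
  }
  mapped <- bitwAnd(flag, 4L) == 0L
  qc_fail <- bitwAnd(flag, 512L) != 0L
  rname <- get(3)
  if (length(refs)) {
    unknown <- mapped & !(rname %in% refs)
    if (any(unknown)) {
      stop_countnet(
        sprintf("SAM line %d: reference '%s' absent from header @SQ records",
                body_idx[which(unknown)[1]], rname[which(unknown)[1]]),
        class = "countnet_validation_error"
      )
    }
  }
  ref_len <- cigar_reference_length(get(6))
  start0 <- ifelse(mapped, pos - 1L, NA_integer_)
  end0 <- ifelse(mapped, pos - 1L + ref_len, NA_integer_)
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-seq_len(11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  read_id <- get(1)
  # fall back to read-id multiplicity among mapped lines when NH is absent
  mult <- table(read_id[mapped])
  inferred <- as.integer(mult[read_id])
  inferred[is.na(inferred)] <- 1L
  hit_count <- ifelse(is.na(nh), pmax(inferred, 1L), nh)
  tibble::tibble(
    read_id = read_id,
    reference = ifelse(mapped, rname, NA_character_),
    start = as.integer(start0),
    end = as.integer(end0),
    mapped = mapped,
    mapq = suppressWarnings(as.integer(get(5))),
    hit_count = as.integer(hit_count),
    qc_fail = qc_fail
  )
}

cigar_reference_length <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    ops <- stringr::str_match_all(cg, "(\\d+)([MIDNSHP=X])")[[1]]
    if (!nrow(ops)) return(0L)
    keep <- ops[, 3] %in% c("M", "D", "N", "=", "X")
    sum(as.integer(ops[keep, 2]))
  }, integer(1), USE.NAMES = FALSE)
}

#' Write alignment records back to SAM text
#'
#' Inverse of [read_sam()] for records whose aligned span is a single gapless
#' match (the form the simulator emits): coordinates are converted back to
#' 1-based SAM positions and the placement count is written as an NH tag.
#'
#' @param alignments Tibble as returned by [read_sam()].
#' @param path Output path.
#' @param reference_lengths Optional named vector of reference sequence
#'   lengths for the `@SQ` header; derived from the alignments when omitted.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, reference_lengths = NULL) {
  if (is.null(reference_lengths)) {
    mapped <- alignments[alignments$mapped, ]
    if (nrow(mapped)) {
      reference_lengths <- tapply(mapped$end, mapped$reference, max)
    } else {
      reference_lengths <- integer()
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ref in names(reference_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ref,
                       as.integer(reference_lengths[[ref]])), con)
  }
  flag <- ifelse(alignments$mapped, 0L, 4L) +
    ifelse(alignments$qc_fail, 512L, 0L)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNH:i:%d",
    alignments$read_id, flag,
    ifelse(alignments$mapped, alignments$reference, "*"),
    ifelse(alignments$mapped, alignments$start + 1L, 0L),
    ifelse(is.na(alignments$mapq), 0L, alignments$mapq),
    ifelse(alignments$mapped,
           sprintf("%dM", alignments$end - alignments$start), "*"),
    alignments$hit_count
  )
  writeLines(lines, con)
  invisible(path)
}
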