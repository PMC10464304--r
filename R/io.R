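#' Read and write chrom.sizes files
#'
#' Two-column whitespace-delimited text: chromosome name, length in bp.
#' The resulting named vector is the single source of truth for
#' chromosome names and lengths; every other reader validates against it.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 2L) stop("chrom.sizes needs two columns")
  cs <- stats::setNames(as.numeric(dt[[2L]]), as.character(dt[[1L]]))
  check_chrom_sizes(cs)
  cs
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Named numeric vector to write.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  check_chrom_sizes(chrom_sizes)
  data.table::fwrite(
    data.table::data.table(names(chrom_sizes),
                           format(chrom_sizes, scientific = FALSE,
                                  trim = TRUE)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

skip_lines <- function(lines) {
  grepl("^(#|track\\b|browser\\b)|^\\s*$", lines)
}

#' Read a BED file of intervals
#'
#' Accepts BED3/BED4/BED6 (extra columns ignored); comment, `track` and
#' `browser` lines are skipped.  Coordinates are 0-based half-open on
#' disk and validated (`0 <= start < end`, within `chrom_sizes` when
#' given); malformed lines are reported with their line number.  The
#' result is a `GRanges` (1-based closed internally, as usual in
#' Bioconductor), sorted by (chrom, start).
#'
#' @param path File path.
#' @param chrom_sizes Optional named vector to validate bounds against.
#' @return Sorted `GRanges`, with `name` (BED4+) and strand (BED6) when
#'   present.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  keep <- !skip_lines(lines)
  if (!any(keep))
    return(GenomicRanges::GRanges())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                 start >= end)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]],
         ": need 0 <= start < end")
  if (!is.null(chrom_sizes)) {
    unk <- which(!chrom %in% names(chrom_sizes))
    if (length(unk))
      stop("BED line ", lineno[unk[1L]], ": unknown chromosome ",
           chrom[unk[1L]])
    oob <- which(end > chrom_sizes[chrom])
    if (length(oob))
      stop("BED line ", lineno[oob[1L]], ": interval beyond chromosome end")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (any(nf >= 4L)) {
    nm <- rep(NA_character_, length(gr))
    has <- nf >= 4L
    nm[has] <- vapply(fields[has], `[[`, character(1), 4L)
    S4Vectors::mcols(gr)$name <- nm
  }
  if (all(nf >= 6L)) {
    str <- vapply(fields, `[[`, character(1), 6L)
    if (all(str %in% c("+", "-", ".")))
      GenomicRanges::strand(gr) <- str
  }
  GenomicRanges::sort(gr)
}

#' @rdname read_bed
#' @param gr `GRanges` to write; a `name` (or `state`) metadata column is
#'   emitted as the 4th BED field.
#' @export
write_bed <- function(gr, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name %||% S4Vectors::mcols(gr)$state
  if (!is.null(nm)) dt$name <- as.character(nm)
  data.table::fwrite(dt[order(chrom, start)], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read and write bedGraph coverage tracks
#'
#' Four-column bedGraph (chrom, 0-based start, half-open end, value).
#' Records must be within bounds and non-overlapping (per chromosome);
#' gaps are interpreted as signal 0; values must be finite.  Violations
#' are reported with line numbers.  On write, adjacent equal-value runs
#' are merged and zero runs are omitted (gap = 0 convention), so a
#' written track re-reads per-base identical.
#'
#' @param path File path.
#' @param chrom_sizes Named vector of chromosome lengths (required: it
#'   fixes the track's genome).
#' @return An `RleList` coverage track.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  lines <- readLines(path)
  keep <- !skip_lines(lines)
  lineno <- which(keep)
  if (!any(keep)) return(flat_track(chrom_sizes))
  fields <- strsplit(lines[keep], "\t| +")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed bedGraph line ", lineno[which(nf < 4L)[1L]],
         ": fewer than 4 fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 |
                 start >= end | !is.finite(value))
  if (length(bad))
    stop("malformed bedGraph line ", lineno[bad[1L]])
  unk <- which(!chrom %in% names(chrom_sizes))
  if (length(unk))
    stop("bedGraph line ", lineno[unk[1L]], ": unknown chromosome ",
         chrom[unk[1L]])
  oob <- which(end > chrom_sizes[chrom])
  if (length(oob))
    stop("bedGraph line ", lineno[oob[1L]],
         ": interval beyond chromosome end")
  ord <- order(chrom, start)
  ov <- which(chrom[ord][-1L] == chrom[ord][-length(ord)] &
                start[ord][-1L] < end[ord][-length(ord)])
  if (length(ov))
    stop("bedGraph line ", lineno[ord[ov[1L] + 1L]],
         ": overlapping records")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               score = value)
  make_track(gr, chrom_sizes)
}

#' @rdname read_bedgraph
#' @param track `RleList` coverage track to write.
#' @export
write_bedgraph <- function(track, path) {
  rows <- list()
  for (chr in names(track)) {
    r <- track[[chr]]
    v <- S4Vectors::runValue(r)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)   # 0-based
    nz <- v != 0
    if (any(nz))
      rows[[chr]] <- data.table::data.table(
        chrom = chr, start = starts[nz], end = ends[nz], value = v[nz])
  }
  dt <- if (length(rows)) data.table::rbindlist(rows)
  else data.table::data.table(chrom = character(), start = integer(),
                              end = integer(), value = numeric())
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path File path.
#' @export
write_tsv_report <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
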