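#' Coverage-track representation
#'
#' Tracks are stored as base-resolution [S4Vectors::RleList] objects, one
#' run-length-encoded numeric vector per chromosome, always covering the
#' full chromosome (uncovered bases are 0).  `chrom_sizes` is the single
#' source of truth for chromosome names and lengths: a named integer
#' vector, as read from a two-column chrom.sizes file.
#'
#' @param gr A `GRanges` with a numeric `score` column (e.g. parsed
#'   bedGraph records).
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @return An `RleList` with one element per chromosome in `chrom_sizes`.
#' @export
make_track <- function(gr, chrom_sizes) {
  check_chrom_sizes(chrom_sizes)
  bad <- setdiff(as.character(GenomeInfoDb::seqnames(gr)@values),
                 names(chrom_sizes))
  if (length(bad))
    stop("track chromosome(s) absent from chrom_sizes: ",
         paste(bad, collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  GenomicRanges::coverage(gr, weight = "score")
}

#' Constant-value track over a genome
#'
#' @inheritParams make_track
#' @param value Signal value at every base.
#' @return An `RleList`.
#' @export
flat_track <- function(chrom_sizes, value = 0) {
  check_chrom_sizes(chrom_sizes)
  methods::as(lapply(chrom_sizes, function(L)
    S4Vectors::Rle(as.numeric(value), L)), "SimpleRleList")
}

check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "") ||
      anyDuplicated(names(chrom_sizes)))
    stop("chrom_sizes must be uniquely named")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chrom_sizes lengths must be finite and > 0")
  invisible(chrom_sizes)
}

track_chrom_sizes <- function(track) {
  stats::setNames(vapply(track, length, numeric(1)), names(track))
}

check_same_genome <- function(tracks) {
  ref <- track_chrom_sizes(tracks[[1L]])
  for (i in seq_along(tracks)[-1L]) {
    cs <- track_chrom_sizes(tracks[[i]])
    if (!identical(names(cs), names(ref)) || !all(cs == ref)) {
      diff <- union(setdiff(names(cs), names(ref)),
                    setdiff(names(ref), names(cs)))
      if (!length(diff))
        diff <- names(ref)[cs[names(ref)] != ref]
      stop("tracks disagree on chromosomes: ", paste(diff, collapse = ", "))
    }
  }
  invisible(ref)
}

#' Pool replicate coverage tracks
#'
#' Per-base arithmetic mean of two or more tracks over the same genome,
#' the replicate-pooling step applied to normalised coverage before any
#' correlation analysis.
#'
#' @param tracks List of >= 2 `RleList` tracks sharing a genome.
#' @return The mean track (`RleList`).
#' @export
pool_tracks <- function(tracks) {
  if (!is.list(tracks) || length(tracks) < 2L)
    stop("pool_tracks needs a list of >= 2 tracks")
  check_same_genome(tracks)
  Reduce(`+`, tracks) / length(tracks)
}

#' log2 ChIP-over-input ratio track
#'
#' Per-base `log2((chip + pc) / (input + pc))` with a pseudocount to keep
#' the ratio defined at uncovered bases, as used when comparing ChIP
#' signal to its input control.
#'
#' @param chip,input Coverage tracks (`RleList`) over the same genome.
#' @param pseudocount Positive value added to both tracks.
#' @return An `RleList`.
#' @export
log2_ratio_track <- function(chip, input, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  check_same_genome(list(chip, input))
  log2((chip + pseudocount) / (input + pseudocount))
}

#' Base-weighted mean signal over intervals
#'
#' Mean track value over each interval, weighting every base equally;
#' bases not covered by the track's source records contribute 0 (tracks
#' are full-genome).  Intervals on chromosomes absent from the track get
#' mean 0 with a warning.
#'
#' @param track Coverage track (`RleList`).
#' @param intervals A `GRanges` (e.g. genome bins or peak regions).
#' @return Numeric vector of per-interval means, in interval order.
#' @export
mean_signal <- function(track, intervals) {
  out <- numeric(length(intervals))
  chrs <- as.character(GenomicRanges::seqnames(intervals))
  for (chr in unique(chrs)) {
    idx <- which(chrs == chr)
    if (!chr %in% names(track)) {
      warning("chromosome ", chr, " absent from track; mean set to 0")
      next
    }
    rng <- IRanges::ranges(intervals[idx])
    if (any(IRanges::end(rng) > length(track[[chr]])))
      stop("interval beyond chromosome end on ", chr)
    out[idx] <- IRanges::viewMeans(IRanges::Views(track[[chr]], rng))
  }
  out
}

#' Tile a genome into fixed-width bins
#'
#' Half-open tiling from position 0 per chromosome; a trailing short bin
#' is kept.  Bins overlapping the blacklist by even one base are removed
#' (not clipped), so retained bin widths stay uniform.
#'
#' @inheritParams make_track
#' @param bin_size Bin width in bp, > 0.
#' @param blacklist Optional `GRanges` of excluded regions.
#' @return A sorted `GRanges` of bins.
#' @export
bin_genome <- function(chrom_sizes, bin_size, blacklist = NULL) {
  check_chrom_sizes(chrom_sizes)
  if (!is.numeric(bin_size) || bin_size <= 0)
    stop("bin_size must be > 0")
  si <- GenomeInfoDb::Seqinfo(names(chrom_sizes), unname(chrom_sizes))
  bins <- GenomicRanges::tileGenome(si, tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  if (!is.null(blacklist) && length(blacklist)) {
    extra <- setdiff(unique(as.character(
      GenomicRanges::seqnames(blacklist))), names(chrom_sizes))
    if (length(extra)) {
      warning("blacklist chromosome(s) not in chrom_sizes ignored: ",
              paste(extra, collapse = ", "))
      blacklist <- blacklist[!as.character(
        GenomicRanges::seqnames(blacklist)) %in% extra]
    }
    hits <- GenomicRanges::findOverlaps(
      bins, blacklist, ignore.strand = TRUE)
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop)) bins <- bins[-drop]
  }
  bins
}

#' Attach per-bin mean signals to bins
#'
#' @param bins `GRanges` of bins (from [bin_genome()]).
#' @param tracks Named list of coverage tracks.
#' @return `bins` with one metadata column of means per track.
#' @export
bin_signal <- function(bins, tracks) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list")
  for (nm in names(tracks))
    S4Vectors::mcols(bins)[[nm]] <- mean_signal(tracks[[nm]], bins)
  bins
}

#' Genome-wide binned Pearson correlation of two tracks
#'
#' Pearson correlation of per-bin mean signals, the standard genome-wide
#' track-similarity statistic (2 kb bins in the reference workflow).
#'
#' @param trackA,trackB Coverage tracks over the same genome.
#' @inheritParams bin_genome
#' @return Pearson r, or `NA` with a warning if either vector has zero
#'   variance.
#' @export
binned_correlation <- function(trackA, trackB, bin_size,
                               blacklist = NULL) {
  cs <- check_same_genome(list(trackA, trackB))
  bins <- bin_genome(cs, bin_size, blacklist)
  a <- mean_signal(trackA, bins)
  b <- mean_signal(trackB, bins)
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L)
    stop("fewer than 3 bins with finite values")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    warning("undefined correlation: zero variance in a track")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])
}
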