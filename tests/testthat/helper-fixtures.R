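# Shared in-code fixtures for the test suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Bind the generics used unqualified in the tests (test environments do
# not reliably see the attached search path).
GRanges <- GenomicRanges::GRanges
IRanges <- IRanges::IRanges
start <- GenomicRanges::start
end <- GenomicRanges::end
width <- GenomicRanges::width

toy_sizes <- c(cA = 10000, cB = 6000)

# Track from explicit runs: list(c(start0, end, value), ...) per chrom,
# 0-based half-open on input like a bedGraph record.
track_from_runs <- function(runs, chrom_sizes = toy_sizes) {
  if (length(runs) == 0)
    return(dualmark::flat_track(chrom_sizes))
  df <- do.call(rbind, lapply(runs, function(r)
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), value = as.numeric(r[[4]]))))
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end), score = df$value)
  dualmark::make_track(gr, chrom_sizes)
}

# Random piecewise-constant track for oracle comparisons.
random_track <- function(chrom_sizes = toy_sizes, seg = 100, seed = 1) {
  set.seed(seed)
  per <- lapply(names(chrom_sizes), function(chr) {
    n <- ceiling(chrom_sizes[[chr]] / seg)
    vals <- stats::runif(n, 0, 10)
    reps <- rep(seg, n)
    reps[n] <- chrom_sizes[[chr]] - seg * (n - 1)
    S4Vectors::Rle(vals, reps)
  })
  names(per) <- names(chrom_sizes)
  methods::as(per, "SimpleRleList")
}

# Per-base numeric vector of one chromosome of a track (brute-force view).
track_vector <- function(track, chr) as.numeric(track[[chr]])

# Shared seqlevels so combining/overlapping fixtures never warns about
# disjoint sequence universes.
test_seqinfo <- GenomeInfoDb::Seqinfo(c("c1", "c2", "cA", "cB", "cQ", "cZ"))

gr_of <- function(chrom, start0, end, ...) {
  GRanges(chrom, IRanges(start0 + 1, end), ..., seqinfo = test_seqinfo)
}

# Small coupled synthetic genome shared by the heavier genome tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- dualmark::genome_spec(
        chrom_sizes = c(chrS1 = 1e6, chrS2 = 1e6), seed = 11)
      cache <<- list(genome = g, sim = dualmark::generate_tracks(g))
    }
    cache
  }
})
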