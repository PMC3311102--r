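# Four-gamete compatible intervals: pairwise test, maximal-k scan, minimal
# full covering, and the coarse-scale density histogram.

#' Four-gamete compatibility of two SDPs
#'
#' Two biallelic sites show no evidence of historical recombination iff at
#' most three of the four possible two-site haplotypes (gametes 00, 01, 10,
#' 11) occur among the strains. Strains with a heterozygous or missing code
#' at either site are excluded from gamete counting; a pair with fewer than
#' two informative strains is compatible by convention.
#'
#' @param a,b integer SDP vectors of equal length (codes -1/0/1/2).
#' @return logical scalar.
#' @export
pair_compatible <- function(a, b) {
  if (length(a) != length(b))
    stop("SDP length mismatch: ", length(a), " vs ", length(b))
  ok <- (a == 0L | a == 1L) & (b == 0L | b == 1L)
  if (!any(ok)) return(TRUE)
  gam <- unique(2L * a[ok] + b[ok])
  length(gam) <= 3L
}

# Minimal left endpoints: L[j] = smallest i (1-based) such that markers
# i..j are pairwise compatible. Uses the hereditary structure: i..j is
# compatible iff i..j-1 is and marker j is compatible with each of
# i..j-1, so L[j] = max(L[j-1], 1 + rightmost k < j incompatible with j).
min_left_extent <- function(gm) {
  m <- n_markers(gm)
  if (m == 0L) stop("empty genotype matrix")
  calls <- gm$calls
  L <- integer(m)
  L[1] <- 1L
  if (m == 1L) return(L)
  for (j in 2:m) {
    lo <- L[j - 1]
    Lj <- lo
    b <- calls[, j]
    if (j - 1 >= lo) {
      for (k in (j - 1):lo) {   # scan right-to-left: first hit is rightmost
        if (!pair_compatible(calls[, k], b)) {
          Lj <- k + 1L
          break
        }
      }
    }
    L[j] <- max(lo, Lj)
  }
  L
}

#' Maximal right extents (maximal-k scan)
#'
#' For each marker i, the largest j such that markers i..j are pairwise
#' four-gamete compatible. Returned as a 0-based index vector aligned to the
#' 0-based marker indices. Non-decreasing by construction.
#'
#' @param gm a single-chromosome [genotype_matrix()].
#' @return integer vector r with r[i+1] = max right extent of marker i
#'   (0-based values).
#' @export
max_right_extent <- function(gm) {
  assert_single_chrom(gm)
  L <- min_left_extent(gm)
  m <- length(L)
  # r[i] = max { j : L[j] <= i }; L is non-decreasing
  r <- integer(m)
  j <- m
  for (i in m:1) {
    while (L[j] > i) j <- j - 1L
    r[i] <- j
  }
  r - 1L   # 0-based
}

#' Minimal full covering of maximal compatible intervals
#'
#' Enumerates the maximal four-gamete compatible intervals along the
#' chromosome and selects a minimal subset that covers every marker: start
#' with the maximal interval covering the first marker with the largest right
#' end, then repeatedly take the maximal interval covering (previous end + 1)
#' with the largest right end. The resulting covering has overlap depth at
#' most 2 at every marker, so intervals can be laid out on two alternating
#' parity rows.
#'
#' @param gm a single-chromosome [genotype_matrix()].
#' @return a data.frame of class `compatible_intervals` with columns
#'   `ordinal` (0-based rank), `parity` ("even"/"odd"), `chrom`,
#'   `start_idx`, `end_idx` (0-based inclusive marker indices),
#'   `start_pos`, `end_pos` (base pairs, 1-based inclusive) and `n_markers`.
#' @export
maximal_covering <- function(gm) {
  ch <- assert_single_chrom(gm)
  L <- min_left_extent(gm)
  m <- length(L)
  r <- max_right_extent(gm) + 1L  # back to 1-based
  starts <- integer(0)
  ends <- integer(0)
  p <- 1L
  repeat {
    R <- r[p]
    i0 <- L[R]   # smallest start reaching R: the maximal interval
    starts <- c(starts, i0)
    ends <- c(ends, R)
    if (R >= m) break
    p <- R + 1L
  }
  k <- length(starts)
  out <- data.frame(
    ordinal = seq_len(k) - 1L,
    parity = ifelse((seq_len(k) - 1L) %% 2L == 0L, "even", "odd"),
    chrom = ch,
    start_idx = starts - 1L,
    end_idx = ends - 1L,
    start_pos = gm$pos[starts],
    end_pos = gm$pos[ends],
    n_markers = ends - starts + 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("compatible_intervals", "data.frame")
  out
}

#' @export
print.compatible_intervals <- function(x, ...) {
  cat("compatible_intervals:", nrow(x), "intervals on", x$chrom[1],
      "covering markers", x$start_idx[1], "-", x$end_idx[nrow(x)], "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

# Depth of coverage (number of covering intervals) at each marker index.
covering_depth <- function(intervals, m) {
  depth <- integer(m)
  for (i in seq_len(nrow(intervals))) {
    idx <- (intervals$start_idx[i]:intervals$end_idx[i]) + 1L
    depth[idx] <- depth[idx] + 1L
  }
  depth
}

#' Density histogram of items over a genomic view
#'
#' Splits the view into `bins` uniform base-pair windows (the last window
#' absorbs any remainder) and counts each item once in the window containing
#' its start position. Items starting outside the view are ignored.
#'
#' @param starts integer vector of item start positions (bp).
#' @param view list/vector with `start`, `end` (1-based inclusive bp).
#' @param bins number of windows (>= 1).
#' @return integer vector of per-bin counts, length `bins`.
#' @export
interval_density_histogram <- function(starts, view, bins) {
  view <- as.list(view)
  v0 <- as.numeric(view$start); v1 <- as.numeric(view$end)
  if (v0 > v1) stop("empty view: start > end")
  if (bins < 1L) stop("bins must be >= 1")
  span <- v1 - v0 + 1
  w <- max(1, floor(span / bins))
  inview <- starts[starts >= v0 & starts <= v1]
  if (length(inview) == 0L) return(integer(bins))
  bin <- pmin(bins, floor((inview - v0) / w) + 1)
  tabulate(bin, nbins = bins)
}
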