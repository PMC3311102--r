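# Haplotype groups per compatible interval and dynamic identity-by-descent.

#' Partition strains into haplotype groups within one compatible interval
#'
#' Single-linkage clustering of strains over the interval's markers. Two
#' strains link when their mismatch fraction over pairwise-informative
#' markers (both calls homozygous, i.e. in \{0,1\}) is at most
#' `mismatch_tol`. A pair with zero informative markers carries no evidence
#' and links by convention only: a strain with no informative pair at all
#' (e.g. all calls missing) joins the group of the lowest-indexed strain it
#' shares such a pair with, instead of bridging evidence-supported groups
#' into one.
#' Group ids are dense from 0 and ordered by each group's smallest strain
#' index.
#'
#' @param gm a [genotype_matrix()].
#' @param interval one row of a [maximal_covering()] result (or any list with
#'   0-based `start_idx`, `end_idx`).
#' @param mismatch_tol allowed mismatch fraction in [0,1]; 0 means exact
#'   identity up to missing/het wildcards.
#' @return list with `interval`, `groups` (0-based integer per strain, named),
#'   `n_groups`, and `members` (list of strain-name vectors per group).
#' @export
assign_haplotype_groups <- function(gm, interval, mismatch_tol = 0) {
  if (mismatch_tol < 0 || mismatch_tol > 1)
    stop("mismatch_tol must be in [0, 1]")
  cols <- (interval$start_idx:interval$end_idx) + 1L
  if (min(cols) < 1L || max(cols) > n_markers(gm))
    stop("interval outside matrix bounds")
  calls <- gm$calls[, cols, drop = FALSE]
  n <- nrow(calls)
  hom <- calls == 0L | calls == 1L
  # single linkage = connected components of the "links" graph; links with
  # zero informative markers are evidence-free and are applied in a second
  # pass so they can attach a strain but never merge two evidence groups
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  uninf <- matrix(FALSE, n, n)
  has_inf <- rep(FALSE, n)
  for (i in seq_len(n)[-1]) {
    for (k in seq_len(i - 1)) {
      ok <- hom[i, ] & hom[k, ]
      ninf <- sum(ok)
      if (ninf == 0L) {
        uninf[i, k] <- uninf[k, i] <- TRUE
        next
      }
      has_inf[i] <- has_inf[k] <- TRUE
      if (sum(calls[i, ok] != calls[k, ok]) / ninf <= mismatch_tol) {
        ri <- find(i); rk <- find(k)
        if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
      }
    }
  }
  # a strain with no informative pair at all joins the group of the
  # lowest-indexed strain it shares an (uninformative) pair with
  for (i in seq_len(n)) {
    if (!has_inf[i] && any(uninf[i, ])) {
      ri <- find(i); rk <- find(which(uninf[i, ])[1])
      if (ri != rk) parent[max(ri, rk)] <- min(ri, rk)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots)) - 1L  # dense, ordered by smallest member
  names(ids) <- gm$strains
  members <- split(gm$strains, ids)
  names(members) <- NULL
  list(interval = interval, groups = ids,
       n_groups = length(members), members = members)
}

#' Haplotype group assignments for every interval of a covering
#'
#' @param gm a [genotype_matrix()].
#' @param intervals a [maximal_covering()] result.
#' @param mismatch_tol see [assign_haplotype_groups()].
#' @return list of per-interval assignments, ordered by interval ordinal.
#' @export
assign_all_haplotypes <- function(gm, intervals, mismatch_tol = 0) {
  lapply(seq_len(nrow(intervals)), function(i)
    assign_haplotype_groups(gm, intervals[i, ], mismatch_tol))
}

#' Dynamic identity-by-descent over a strain subset
#'
#' A compatible interval is IBD-positive for the selected strains when they
#' all fall in one haplotype group there; maximal runs of consecutive
#' IBD-positive intervals are merged into blocks. Genomic bounds of a block
#' are the union of its constituent interval bounds (marker-index bounds are
#' authoritative where neighboring intervals share boundary base pairs).
#'
#' @param assignments per-interval assignment list from
#'   [assign_all_haplotypes()], ordered by ordinal.
#' @param selected non-empty character vector of strain names.
#' @return data.frame with columns `chrom`, `start`, `end` (bp),
#'   `start_idx`, `end_idx` (0-based marker indices),
#'   `n_intervals_merged`; zero rows if no interval is IBD-positive.
#' @export
compute_ibd <- function(assignments, selected) {
  if (length(selected) == 0L) stop("selected strain set must be non-empty")
  strains <- names(assignments[[1]]$groups)
  unknown <- setdiff(selected, strains)
  if (length(unknown) > 0)
    stop("unknown strain name(s): ", paste(unknown, collapse = ", "))
  pos <- vapply(assignments, function(a)
    length(unique(a$groups[selected])) == 1L, logical(1))
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), start_idx = integer(0),
                    end_idx = integer(0), n_intervals_merged = integer(0),
                    stringsAsFactors = FALSE)
  for (k in keep) {
    iv1 <- assignments[[starts[k]]]$interval
    iv2 <- assignments[[ends[k]]]$interval
    out <- rbind(out, data.frame(
      chrom = iv1$chrom, start = iv1$start_pos, end = iv2$end_pos,
      start_idx = iv1$start_idx, end_idx = iv2$end_idx,
      n_intervals_merged = ends[k] - starts[k] + 1L,
      stringsAsFactors = FALSE))
  }
  out
}
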