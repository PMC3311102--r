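# Haplotype mosaic colorings and position-radiating strain sorting.

#' Haplotype color palette
#'
#' Fixed ordered palette of distinguishable colors; the color INDEX (0-based)
#' is the semantic unit throughout, hex values are only used at render time.
#'
#' @return character vector of hex colors.
#' @export
haplotype_palette <- function() {
  c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
    "#8C564B", "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF",
    "#AEC7E8", "#FFBB78", "#98DF8A", "#FF9896", "#C5B0D5",
    "#C49C94", "#F7B6D2", "#C7C7C7", "#DBDB8D", "#9EDAE5",
    "#393B79", "#637939", "#8C6D31", "#843C39", "#7B4173")
}

#' Subspecies display colors
#'
#' domesticus = blue, musculus = red, castaneus = green.
#'
#' @return named character vector of hex colors.
#' @export
subspecies_colors <- function() {
  c(domesticus = "#0000FF", musculus = "#FF0000", castaneus = "#00A000")
}

new_color_mosaic <- function(colors, assignments) {
  structure(colors, class = "color_mosaic",
            intervals = do.call(rbind, lapply(assignments, function(a)
              as.data.frame(a$interval))))
}

#' @export
print.color_mosaic <- function(x, ...) {
  cat("color_mosaic:", nrow(x), "strains x", ncol(x), "intervals,",
      length(unique(as.vector(x))), "distinct colors\n")
  invisible(x)
}

# Maximum-weight bipartite matching of current groups (columns of `weight`)
# to previous groups (rows). Returns, per current group, the 1-based matched
# previous-group index or NA. The positive-weight graph is split into
# connected components; each is solved exactly by depth-first search over the
# current-group side (groups ascending; previous candidates ordered by their
# color, then index; "unmatched" tried last), keeping the first maximum found
# so ties resolve deterministically toward smaller previous colors. A
# component whose current side exceeds `exact_limit` falls back to greedy
# matching by descending weight with the same tie order.
boundary_matching <- function(weight, prev_color, exact_limit = 12L) {
  np <- nrow(weight); nc <- ncol(weight)
  res <- rep(NA_integer_, nc)
  if (np == 0L || nc == 0L) return(res)
  # connected components over the bipartite positive-weight graph
  comp_p <- rep(0L, np); comp_c <- rep(0L, nc); ncomp <- 0L
  for (c0 in seq_len(nc)) {
    if (comp_c[c0] > 0L || !any(weight[, c0] > 0L)) next
    ncomp <- ncomp + 1L
    queue_c <- c0
    while (length(queue_c) > 0L) {
      cc <- queue_c[[1L]]; queue_c <- queue_c[-1L]
      if (comp_c[cc] > 0L) next
      comp_c[cc] <- ncomp
      for (p in which(weight[, cc] > 0L & comp_p == 0L)) {
        comp_p[p] <- ncomp
        queue_c <- c(queue_c, which(weight[p, ] > 0L & comp_c == 0L))
      }
    }
  }
  for (k in seq_len(ncomp)) {
    cs <- which(comp_c == k)
    ps <- which(comp_p == k)
    if (length(cs) > exact_limit || length(ps) > exact_limit) {
      res[cs] <- greedy_matching(weight, prev_color, cs, ps)
      next
    }
    best <- rep(NA_integer_, length(cs))
    best_w <- -1L
    cur <- rep(NA_integer_, length(cs))
    used <- rep(FALSE, np)
    dfs <- function(i, acc) {
      if (i > length(cs)) {
        if (acc > best_w) { best_w <<- acc; best <<- cur }
        return(invisible())
      }
      # prune: remaining columns can add at most their best free weight
      ub <- acc
      for (j in i:length(cs)) {
        w <- weight[ps, cs[j]]
        w[used[ps]] <- 0L
        ub <- ub + max(w, 0L)
      }
      if (ub <= best_w) return(invisible())
      cands <- ps[weight[ps, cs[i]] > 0L & !used[ps]]
      cands <- cands[order(prev_color[cands], cands)]
      for (p in cands) {
        used[p] <<- TRUE; cur[i] <<- p
        dfs(i + 1L, acc + weight[p, cs[i]])
        used[p] <<- FALSE; cur[i] <<- NA_integer_
      }
      dfs(i + 1L, acc)  # leave current group i unmatched
    }
    dfs(1L, 0L)
    res[cs] <- best
  }
  res
}

# Greedy fallback: descending shared-strain count, ties to the smaller
# previous color then the smaller current group index.
greedy_matching <- function(weight, prev_color, cs, ps) {
  out <- rep(NA_integer_, length(cs))
  used <- rep(FALSE, nrow(weight))
  cand <- which(weight[ps, cs, drop = FALSE] > 0L, arr.ind = TRUE)
  if (nrow(cand) > 0L) {
    w <- weight[cbind(ps[cand[, 1L]], cs[cand[, 2L]])]
    o <- order(-w, prev_color[ps[cand[, 1L]]], cs[cand[, 2L]])
    cand <- cand[o, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      p <- ps[cand[r, 1L]]; ci <- cand[r, 2L]
      if (!used[p] && is.na(out[ci])) {
        out[ci] <- p
        used[p] <- TRUE
      }
    }
  }
  out
}

#' Default transition-minimizing haplotype coloring
#'
#' Assigns a palette index to every (strain, interval) cell so that strains
#' share a color within an interval iff they share a haplotype group, reusing
#' colors across consecutive intervals to minimize color transitions. The
#' first interval's groups take colors 0..k-1 by group id; each later
#' interval's groups are matched to the previous interval's groups by a
#' maximum-weight bipartite matching on shared-strain counts (exact over
#' each connected component of the sharing graph, with a deterministic
#' tie-break favouring the smaller previous color, then the smaller current
#' group id); matched groups inherit the color, unmatched groups take the
#' smallest palette index unused in the interval. Because the matching at
#' each boundary depends only on the two adjacent partitions, maximizing
#' each boundary independently minimizes the total number of color
#' transitions over all valid colorings.
#'
#' @param assignments per-interval assignments from [assign_all_haplotypes()].
#' @return a `color_mosaic`: integer matrix strains x intervals of 0-based
#'   color indices, rownames = strains.
#' @export
default_coloring <- function(assignments) {
  strains <- names(assignments[[1]]$groups)
  ti <- length(assignments)
  colors <- matrix(NA_integer_, nrow = length(strains), ncol = ti,
                   dimnames = list(strains, NULL))
  prev_group_color <- NULL
  prev_groups <- NULL
  for (t in seq_len(ti)) {
    g <- assignments[[t]]$groups
    ng <- assignments[[t]]$n_groups
    if (t == 1L) {
      gcol <- seq_len(ng) - 1L
    } else {
      # weight[p, c] = strains shared between previous group p and current c
      weight <- matrix(0L, nrow = length(prev_group_color), ncol = ng)
      for (s in seq_along(strains))
        weight[prev_groups[s] + 1L, g[s] + 1L] <-
          weight[prev_groups[s] + 1L, g[s] + 1L] + 1L
      match_prev <- boundary_matching(weight, prev_group_color)
      gcol <- prev_group_color[match_prev]  # NA where unmatched
      for (cc in which(is.na(gcol))) {
        free <- setdiff(0:(ng + length(prev_group_color)), gcol)
        gcol[cc] <- min(free)
      }
    }
    colors[, t] <- gcol[g + 1L]
    prev_group_color <- gcol
    prev_groups <- g
  }
  new_color_mosaic(colors, assignments)
}

#' Order-based recoloring
#'
#' Recolors the mosaic according to a display order: in each interval, a
#' strain's color is the display rank (0-based) of the earliest-ranked
#' displayed strain sharing its haplotype group. The topmost strain is thus
#' a single color genome-wide, and equal colors correspond exactly to equal
#' groups among the displayed strains.
#'
#' @param assignments per-interval assignments from [assign_all_haplotypes()].
#' @param display_order ordered character vector of displayed strains
#'   (subset of the panel), non-empty.
#' @return a `color_mosaic` over the displayed strains only.
#' @export
order_recoloring <- function(assignments, display_order) {
  if (length(display_order) == 0L) stop("display_order must be non-empty")
  strains <- names(assignments[[1]]$groups)
  unknown <- setdiff(display_order, strains)
  if (length(unknown) > 0)
    stop("unknown strain name(s): ", paste(unknown, collapse = ", "))
  ti <- length(assignments)
  colors <- matrix(NA_integer_, nrow = length(display_order), ncol = ti,
                   dimnames = list(display_order, NULL))
  for (t in seq_len(ti)) {
    g <- assignments[[t]]$groups[display_order]
    # earliest display rank per group id among displayed strains
    first_rank <- tapply(seq_along(display_order) - 1L, g, min)
    colors[, t] <- as.integer(first_rank[as.character(g)])
  }
  new_color_mosaic(colors, assignments)
}

#' Count color transitions between consecutive intervals
#'
#' @param mosaic a `color_mosaic`.
#' @return total number of (strain, boundary) cells whose color changes.
#' @export
count_transitions <- function(mosaic) {
  if (ncol(mosaic) < 2L) return(0L)
  sum(mosaic[, -1L, drop = FALSE] != mosaic[, -ncol(mosaic), drop = FALSE])
}

# Interval (1-based list index) containing a base-pair position; a position
# inside the overlap of two intervals maps to the one with the smaller start.
interval_at_position <- function(assignments, position) {
  iv <- do.call(rbind, lapply(assignments, function(a)
    data.frame(start = a$interval$start_pos, end = a$interval$end_pos)))
  hit <- which(iv$start <= position & position <= iv$end)
  if (length(hit) == 0L) return(NA_integer_)
  hit[which.min(iv$start[hit])]
}

#' Sort strains by haplotype radiating from a position
#'
#' Stable lexicographic sort of the strains on their haplotype group ids
#' over the intervals intersecting the view, ordered by radiation from the
#' interval containing `position` (that interval first, then alternately the
#' next interval to the right and to the left). Ties persisting at the view
#' edges keep the `initial_order`.
#'
#' @param assignments per-interval assignments from [assign_all_haplotypes()].
#' @param position base-pair position; must lie inside `view`.
#' @param view list/vector with `start`, `end` (bp).
#' @param initial_order starting strain order (defaults to panel order).
#' @return reordered character vector of strain names.
#' @export
sort_strains_at <- function(assignments, position, view,
                            initial_order = names(assignments[[1]]$groups)) {
  view <- as.list(view)
  if (position < view$start || position > view$end)
    stop("position ", position, " outside view [", view$start, ", ",
         view$end, "]")
  iv <- do.call(rbind, lapply(assignments, function(a)
    data.frame(start = a$interval$start_pos, end = a$interval$end_pos)))
  in_view <- which(iv$end >= view$start & iv$start <= view$end)
  t0 <- interval_at_position(assignments, position)
  if (is.na(t0)) t0 <- in_view[which.min(abs(
    (iv$start[in_view] + iv$end[in_view]) / 2 - position))]
  # radiation order: t0, t0+1, t0-1, t0+2, t0-2, ... restricted to the view
  seq_rad <- t0
  d <- 1L
  repeat {
    r <- t0 + d; l <- t0 - d
    added <- FALSE
    if (r %in% in_view) { seq_rad <- c(seq_rad, r); added <- TRUE }
    if (l %in% in_view) { seq_rad <- c(seq_rad, l); added <- TRUE }
    if (!added && r > max(in_view) && l < min(in_view)) break
    d <- d + 1L
  }
  keys <- lapply(seq_rad, function(t) assignments[[t]]$groups[initial_order])
  ord <- do.call(order, c(keys, list(seq_along(initial_order)),
                          method = "radix"))
  initial_order[ord]
}

#' Export a color mosaic as a delimited table
#'
#' One row per (strain, interval): strain, interval ordinal, chrom, start,
#' end, color index.
#'
#' @param mosaic a `color_mosaic`.
#' @param path output path (tab-separated).
#' @export
write_mosaic_tsv <- function(mosaic, path) {
  iv <- attr(mosaic, "intervals")
  rows <- expand.grid(strain = rownames(mosaic),
                      t = seq_len(ncol(mosaic)), stringsAsFactors = FALSE)
  df <- data.frame(strain = rows$strain,
                   ordinal = iv$ordinal[rows$t],
                   chrom = iv$chrom[rows$t],
                   start = iv$start_pos[rows$t],
                   end = iv$end_pos[rows$t],
                   color = mosaic[cbind(match(rows$strain, rownames(mosaic)),
                                        rows$t)])
  df <- df[order(df$strain, df$ordinal), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
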