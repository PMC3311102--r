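# Local phylogeny per compatible interval: consensus distances between
# haplotype groups, neighbor-joining, leaf support, Newick export.

# Per-group consensus over the interval's markers: majority homozygous
# allele among members (het/missing excluded), NA on ties or no data.
group_consensus <- function(gm, interval, assignment) {
  cols <- (interval$start_idx:interval$end_idx) + 1L
  calls <- gm$calls[, cols, drop = FALSE]
  ng <- assignment$n_groups
  cons <- matrix(NA_integer_, nrow = ng, ncol = length(cols))
  for (g in seq_len(ng)) {
    sub <- calls[assignment$groups == g - 1L, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      n0 <- sum(v == 0L); n1 <- sum(v == 1L)
      if (n0 > n1) cons[g, j] <- 0L
      else if (n1 > n0) cons[g, j] <- 1L
      # tie (including 0 vs 0) -> NA
    }
  }
  cons
}

#' Distance matrix between haplotype groups of an interval
#'
#' Distance between two groups = fraction of markers at which their
#' consensus alleles differ, among markers where both consensuses are
#' defined; a pair with no comparable marker gets distance 1 with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param interval one covering-interval row.
#' @param assignment output of [assign_haplotype_groups()] for the interval.
#' @return symmetric numeric matrix with dimnames "g0", "g1", ...
#' @export
group_distance_matrix <- function(gm, interval, assignment) {
  ng <- assignment$n_groups
  if (ng < 2L) stop("need at least 2 haplotype groups to build a tree")
  cons <- group_consensus(gm, interval, assignment)
  d <- matrix(0, ng, ng, dimnames = list(paste0("g", 0:(ng - 1)),
                                         paste0("g", 0:(ng - 1))))
  for (i in seq_len(ng - 1)) for (k in (i + 1):ng) {
    ok <- !is.na(cons[i, ]) & !is.na(cons[k, ])
    if (!any(ok)) {
      warning("groups g", i - 1, " and g", k - 1,
              " share no comparable marker; distance set to 1")
      d[i, k] <- d[k, i] <- 1
    } else {
      d[i, k] <- d[k, i] <- mean(cons[i, ok] != cons[k, ok])
    }
  }
  d
}

#' Neighbor-joining tree over haplotype groups
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' the Q-criterion, with the closed-form branch lengths; a negative branch
#' length is clamped to 0 and the excess moved to its sister branch. Two
#' leaves produce a single split of the pairwise distance. The result wraps
#' an `ape::phylo` tree.
#'
#' @param d symmetric distance matrix with zero diagonal (dimnames = leaf
#'   names).
#' @param leaf_info optional data.frame of per-leaf annotation (row order =
#'   leaf order of `d`): member strains, support, subspecies labels.
#' @return object of class `haplo_tree`: list with `phylo` (ape tree) and
#'   `leaf_info`.
#' @export
neighbor_joining <- function(d, leaf_info = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12) || any(d < 0) ||
      any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("g", seq_len(n) - 1L)
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        labels[1], d[1, 2] / 2,
                                        labels[2], d[1, 2] / 2))
    return(structure(list(phylo = tr, leaf_info = leaf_info),
                     class = "haplo_tree"))
  }
  # node bookkeeping in ape convention: tips 1..n, internals n+1, n+2, ...
  active <- seq_len(n)           # node ids of current working taxa
  D <- d
  next_node <- n + 1L
  edges <- matrix(0L, 0, 2)
  elen <- numeric(0)
  while (length(active) > 2L) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]  # first minimum: ties by
    i <- min(ij); j <- max(ij)                     # row-major order
    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    # clamp negatives, pushing the excess onto the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    if (li < 0) li <- 0
    if (lj < 0) lj <- 0
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    elen <- c(elen, li, lj)
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], u)
  }
  # final edge between the last two working taxa; at least one is internal
  # for n >= 3, and the last-created internal node is always among them
  if (active[1] <= n) active <- active[c(2, 1)]
  edges <- rbind(edges, c(active[1], active[2]))
  elen <- c(elen, D[1, 2])
  Nnode <- next_node - 1L - n
  tr <- list(edge = edges, edge.length = elen, tip.label = labels,
             Nnode = Nnode)
  class(tr) <- "phylo"
  tr <- reorient_phylo(tr, n)
  structure(list(phylo = tr, leaf_info = leaf_info), class = "haplo_tree")
}

# Re-root the edge list so every edge points parent -> child from the
# highest-numbered internal node (ape requires a consistent orientation).
reorient_phylo <- function(tr, ntip) {
  root <- ntip + tr$Nnode  # last-created internal node
  adj <- list()
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    adj[[as.character(a)]] <- rbind(adj[[as.character(a)]], c(b, e))
    adj[[as.character(b)]] <- rbind(adj[[as.character(b)]], c(a, e))
  }
  new_edge <- matrix(0L, 0, 2)
  new_len <- numeric(0)
  visited <- rep(FALSE, ntip + tr$Nnode)
  stack <- root
  visited[root] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      w <- nb[r, 1]
      if (!visited[w]) {
        visited[w] <- TRUE
        new_edge <- rbind(new_edge, c(v, w))
        new_len <- c(new_len, tr$edge.length[nb[r, 2]])
        stack <- c(stack, w)
      }
    }
  }
  tr$edge <- new_edge
  tr$edge.length <- new_len
  # renumber internal nodes in preorder as ape prefers: root = ntip+1
  internal <- unique(new_edge[new_edge[, 1] > ntip, 1])
  internal <- internal[order(match(internal, new_edge[, 1]))]
  map <- integer(ntip + tr$Nnode)
  map[seq_len(ntip)] <- seq_len(ntip)
  map[internal] <- ntip + seq_along(internal)
  tr$edge[] <- map[tr$edge]
  tr
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("haplo_tree:", length(x$phylo$tip.label), "haplotype-group leaves\n")
  cat(ape::write.tree(x$phylo), "\n")
  if (!is.null(x$leaf_info)) print(x$leaf_info)
  invisible(x)
}

#' Per-leaf support: private-difference markers
#'
#' `supporting_snps` of a leaf = number of interval markers at which all of
#' its member strains share one defined (homozygous) allele that differs
#' from the consensus of at least one other leaf; `confidence` = that count
#' divided by the interval's marker count.
#'
#' @param gm a [genotype_matrix()].
#' @param interval one covering-interval row.
#' @param assignment output of [assign_haplotype_groups()].
#' @return data.frame with `leaf`, `supporting_snps`, `confidence`,
#'   `strains` (comma-joined members).
#' @export
leaf_support <- function(gm, interval, assignment) {
  cols <- (interval$start_idx:interval$end_idx) + 1L
  calls <- gm$calls[, cols, drop = FALSE]
  ng <- assignment$n_groups
  cons <- group_consensus(gm, interval, assignment)
  supp <- integer(ng)
  for (g in seq_len(ng)) {
    sub <- calls[assignment$groups == g - 1L, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      if (!all(v %in% c(0L, 1L)) || length(unique(v)) != 1L) next
      a <- v[1]
      others <- cons[-g, j]
      if (any(!is.na(others) & others != a)) supp[g] <- supp[g] + 1L
    }
  }
  data.frame(
    leaf = paste0("g", 0:(ng - 1)),
    supporting_snps = supp,
    confidence = supp / length(cols),
    strains = vapply(assignment$members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
}

#' Build the local phylogeny for one compatible interval
#'
#' Convenience wrapper: haplotype groups -> consensus distance matrix ->
#' neighbor-joining tree with leaf support attached. Optional subspecies
#' labels (from the origin HMM at the interval midpoint) annotate strains.
#'
#' @param gm a [genotype_matrix()].
#' @param interval one covering-interval row.
#' @param mismatch_tol haplotype grouping tolerance.
#' @param subspecies_labels optional named strain -> subspecies vector.
#' @return a `haplo_tree`.
#' @export
local_tree <- function(gm, interval, mismatch_tol = 0,
                       subspecies_labels = NULL) {
  assignment <- assign_haplotype_groups(gm, interval, mismatch_tol)
  d <- group_distance_matrix(gm, interval, assignment)
  info <- leaf_support(gm, interval, assignment)
  if (!is.null(subspecies_labels)) {
    info$subspecies <- vapply(assignment$members, function(ms)
      paste(ifelse(ms %in% names(subspecies_labels),
                   subspecies_labels[ms], "unknown"), collapse = ","),
      character(1))
  }
  neighbor_joining(d, info)
}

#' Write a tree as Newick, with a leaf sidecar table
#'
#' @param tree a `haplo_tree`.
#' @param path Newick output path.
#' @param leaves_path optional tab-separated sidecar (leaf, confidence,
#'   supporting_snps, strains).
#' @export
write_newick <- function(tree, path, leaves_path = NULL) {
  ape::write.tree(tree$phylo, file = path)
  if (!is.null(leaves_path) && !is.null(tree$leaf_info))
    utils::write.table(tree$leaf_info, leaves_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
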