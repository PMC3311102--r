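whole_interval <- function(gm) maximal_covering(gm)[1, ]

test_that("group consensus distances follow the defined-marker fraction", {
  gm <- gm_strings(c("0000", "0000", "1111", "1111"))
  iv <- whole_interval(gm)
  a <- assign_haplotype_groups(gm, iv, 0)
  d <- group_distance_matrix(gm, iv, a)
  expect_equal(unname(d["g0", "g1"]), 1.0)
  expect_equal(diag(d), c(g0 = 0, g1 = 0))
  # identical consensus -> 0 (distinct because of a wildcard marker)
  gm0 <- gm_strings(c("000N", "0002"))
  iv0 <- whole_interval(gm0)
  a0 <- assign_haplotype_groups(gm0, iv0, 0)
  expect_equal(a0$n_groups, 1)
  # undefined consensus markers drop out: 10 markers; marker 1 ties 0-1
  # inside group {C,D} (consensus NA there), consensuses differ at 6 of the
  # 9 remaining defined markers (5 and 6-10)
  gm1 <- gm_codes(rbind(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1),
                        c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1),
                        c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0),
                        c(1, 0, 0, 0, 1, 0, 0, 0, 0, 0)))
  iv1 <- list(chrom = "chr1", start_idx = 0, end_idx = 9)
  a1 <- list(interval = iv1, groups = c(A = 0L, B = 0L, C = 1L, D = 1L),
             n_groups = 2, members = list(c("A", "B"), c("C", "D")))
  d1 <- group_distance_matrix(gm1, iv1, a1)
  expect_equal(unname(d1["g0", "g1"]), 6 / 9)
  expect_error(group_distance_matrix(gm, iv,
    list(interval = iv, groups = c(A = 0L, B = 0L, C = 0L, D = 0L),
         n_groups = 1, members = list(LETTERS[1:4]))), "2 haplotype groups")
})

test_that("groups with no comparable markers get distance 1 with warning", {
  gm <- gm_strings(c("00NN", "00NN", "NN11", "NN11"))
  iv <- list(chrom = "chr1", start_idx = 0, end_idx = 3)
  a <- list(interval = iv, groups = c(A = 0L, B = 0L, C = 1L, D = 1L),
            n_groups = 2, members = list(c("A", "B"), c("C", "D")))
  expect_warning(d <- group_distance_matrix(gm, iv, a), "no comparable")
  expect_equal(unname(d["g0", "g1"]), 1.0)
})

test_that("two-leaf tree is a single split of the pairwise distance", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
              dimnames = list(c("g0", "g1"), c("g0", "g1")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$phylo$tip.label), c("g0", "g1"))
  expect_equal(sum(tr$phylo$edge.length), 0.3)
  cd <- ape::cophenetic.phylo(tr$phylo)
  expect_equal(cd["g0", "g1"], 0.3)
})

test_that("three-leaf branch lengths follow the closed form", {
  dab <- 0.4; dac <- 0.6; dbc <- 0.8
  d <- matrix(c(0, dab, dac, dab, 0, dbc, dac, dbc, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)$phylo
  # star tree: leaf branch a = (d_ab + d_ac - d_bc)/2, etc.
  depth <- ape::node.depth.edgelength(tr)[seq_len(3)]
  names(depth) <- tr$tip.label
  expect_equal(depth[["a"]], (dab + dac - dbc) / 2)
  expect_equal(depth[["b"]], (dab + dbc - dac) / 2)
  expect_equal(depth[["c"]], (dac + dbc - dab) / 2)
})

test_that("NJ recovers additive metrics exactly for 4-8 leaves", {
  set.seed(41)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, rooted = FALSE)
    gen$edge.length <- round(stats::runif(nrow(gen$edge), 0.05, 1), 3)
    D <- ape::cophenetic.phylo(gen)
    ord <- sample(rownames(D))
    D <- D[ord, ord]
    fit <- neighbor_joining(D)$phylo
    expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(fit)), 0,
                 ignore_attr = TRUE)
    D2 <- ape::cophenetic.phylo(fit)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
    # independent cross-check against ape's NJ topology
    expect_equal(ape::dist.topo(ape::unroot(fit),
                                ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("negative branch lengths are clamped with excess on the sister", {
  # non-additive matrix known to drive one NJ branch negative
  d <- matrix(c(0, 0.1, 0.4, 0.5,
                0.1, 0, 0.45, 0.55,
                0.4, 0.45, 0, 0.05,
                0.5, 0.55, 0.05, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)$phylo
  expect_true(all(tr$edge.length >= 0))
  cd <- ape::cophenetic.phylo(tr)
  expect_true(isSymmetric(cd))
  expect_true(all(cd >= 0))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("leaf support counts private-difference markers", {
  # leaf g1 has a private allele at every marker; g0 and g2 identical
  gm <- gm_strings(c("000", "000", "111", "111", "000"))
  iv <- list(chrom = "chr1", start_idx = 0, end_idx = 2)
  a <- list(interval = iv,
            groups = c(A = 0L, B = 0L, C = 1L, D = 1L, E = 2L),
            n_groups = 3,
            members = list(c("A", "B"), c("C", "D"), "E"))
  supp <- leaf_support(gm, iv, a)
  expect_equal(supp$supporting_snps, c(3L, 3L, 3L))
  expect_equal(supp$confidence, c(1, 1, 1))
  # all groups identical everywhere: zero support
  gm0 <- gm_strings(c("000", "000"))
  a0 <- list(interval = iv, groups = c(A = 0L, B = 1L), n_groups = 2,
             members = list("A", "B"))
  supp0 <- leaf_support(gm0, iv, a0)
  expect_equal(supp0$supporting_snps, c(0L, 0L))
  expect_equal(supp0$confidence, c(0, 0))
})

test_that("leaf support on a mixed toy matches an exhaustive scan", {
  gm <- gm_strings(c("010011", "010011", "110000", "0100N1"))
  iv <- list(chrom = "chr1", start_idx = 0, end_idx = 5)
  a <- list(interval = iv,
            groups = c(A = 0L, B = 0L, C = 1L, D = 2L), n_groups = 3,
            members = list(c("A", "B"), "C", "D"))
  supp <- leaf_support(gm, iv, a)
  # hand/exhaustive count: g0 consensus 010011, g1 110000, g2 0100N1
  # g0 differs from g1 at markers 1,5,6 (all members defined+equal) -> 3
  # g1 differs from g0/g2 at 1,5,6 and from g0 at 6 -> markers 1,5,6 -> 3
  # g2 defined at 1,2,3,4,6; differs from g1 at 1,6 -> 2
  expect_equal(supp$supporting_snps, c(3L, 3L, 2L))
})

test_that("Newick output round-trips through a standard parser", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, 2,
              dimnames = list(c("g0", "g1"), c("g0", "g1")))
  tr <- neighbor_joining(d, leaf_info = data.frame(
    leaf = c("g0", "g1"), supporting_snps = c(2L, 1L),
    confidence = c(1, 0.5), strains = c("A,B", "C")))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  sidecar <- withr::local_tempfile(fileext = ".tsv")
  write_newick(tr, nwk, sidecar)
  back <- ape::read.tree(nwk)
  expect_equal(sort(back$tip.label), c("g0", "g1"))
  expect_equal(ape::cophenetic.phylo(back)["g0", "g1"], 0.3,
               tolerance = 1e-9)
  side <- read.delim(sidecar)
  expect_equal(side$strains, c("A,B", "C"))
  # 4-leaf additive tree: re-parsed distances match the input matrix
  gen <- ape::rtree(4, rooted = FALSE)
  gen$edge.length <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  D <- ape::cophenetic.phylo(gen)
  fit <- neighbor_joining(D)
  write_newick(fit, nwk)
  reD <- ape::cophenetic.phylo(ape::read.tree(nwk))[rownames(D), colnames(D)]
  expect_lt(max(abs(reD - D)), 1e-6)  # Newick text precision
})

test_that("every SDP in a clean compatible interval maps to one tree edge", {
  set.seed(47)
  sim <- simulate_panel(sim_params(n_strains = 16, n_markers = 120,
                                   miss_rate = 0, err_rate = 0, seed = 14))
  gm <- sim$matrix
  iv <- maximal_covering(gm)
  tested <- 0
  for (k in seq_len(nrow(iv))) {
    a <- assign_haplotype_groups(gm, iv[k, ], 0)
    if (a$n_groups < 3) next
    tested <- tested + 1
    tr <- local_tree(gm, iv[k, ], 0)$phylo
    # leaf bipartitions induced by each tree edge
    splits <- lapply(seq_len(nrow(tr$edge)), function(e) {
      child <- tr$edge[e, 2]
      desc <- if (child <= length(tr$tip.label)) tr$tip.label[child]
              else ape::extract.clade(tr, child)$tip.label
      sort(desc)
    })
    for (j in (iv$start_idx[k]:iv$end_idx[k]) + 1) {
      col <- gm$calls[, j]
      if (length(unique(col)) < 2) next  # monomorphic: trivial split
      carriers <- sort(unique(paste0("g", a$groups[col == 1L])))
      non <- sort(unique(paste0("g", a$groups[col == 0L])))
      if (length(intersect(carriers, non)) > 0) next  # group-internal noise
      hit <- any(vapply(splits, function(s)
        identical(s, carriers) || identical(s, sort(setdiff(
          tr$tip.label, carriers))), logical(1)))
      expect_true(hit)
    }
    if (tested >= 5) break
  }
  expect_gte(tested, 1)
})
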