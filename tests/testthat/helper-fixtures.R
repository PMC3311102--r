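# Fixture builders and brute-force oracles, independent of the package's
# own algorithm paths.

# genotype matrix from an integer code matrix (strains x markers)
gm_codes <- function(codes, pos = NULL, chrom = "chr1", strains = NULL) {
  codes <- as.matrix(codes)
  if (is.null(strains)) strains <- LETTERS[seq_len(nrow(codes))]
  if (is.null(pos)) pos <- seq_len(ncol(codes)) * 100L
  genotype_matrix(codes, strains, chrom, pos)
}

# genotype matrix from per-strain call strings over the alphabet 0/1/2/N
gm_strings <- function(strings, ...) {
  codes <- t(vapply(strsplit(strings, ""), function(ch) {
    v <- suppressWarnings(as.integer(ch))
    v[ch == "N"] <- -1L
    v
  }, integer(nchar(strings[1]))))
  gm_codes(codes, ...)
}

random_gm <- function(n_strains, n_markers,
                      p_minor = 0.4, p_het = 0.05, p_miss = 0.05) {
  codes <- matrix(sample(c(0L, 1L, 2L, -1L), n_strains * n_markers,
                         replace = TRUE,
                         prob = c(1 - p_minor - p_het - p_miss, p_minor,
                                  p_het, p_miss)),
                  nrow = n_strains)
  gm_codes(codes)
}

# --- four-gamete oracle, written from the definition -----------------------

oracle_pair_ok <- function(a, b) {
  keep <- a %in% c(0L, 1L) & b %in% c(0L, 1L)
  nrow(unique(cbind(a[keep], b[keep]))) <= 3L
}

oracle_all_pairs_ok <- function(gm, i, j) {
  if (i == j) return(TRUE)
  for (x in i:(j - 1)) for (y in (x + 1):j)
    if (!oracle_pair_ok(gm$calls[, x], gm$calls[, y])) return(FALSE)
  TRUE
}

# max right extents by direct enumeration (1-based in, 0-based out)
oracle_right_extents <- function(gm) {
  m <- ncol(gm$calls)
  r <- integer(m)
  for (i in seq_len(m)) {
    j <- i
    while (j < m && oracle_all_pairs_ok(gm, i, j + 1)) j <- j + 1
    r[i] <- j
  }
  r - 1L
}

# enumerate every compatible interval, filter to maximal, cover greedily
oracle_covering <- function(gm) {
  m <- ncol(gm$calls)
  ivs <- list()
  for (i in seq_len(m)) for (j in i:m)
    if (oracle_all_pairs_ok(gm, i, j))
      ivs[[length(ivs) + 1]] <- c(i, j)
  ivs <- do.call(rbind, ivs)
  maximal <- ivs[!vapply(seq_len(nrow(ivs)), function(k)
    any(ivs[, 1] <= ivs[k, 1] & ivs[, 2] >= ivs[k, 2] &
        (ivs[, 1] < ivs[k, 1] | ivs[, 2] > ivs[k, 2])), logical(1)), ,
    drop = FALSE]
  chosen <- list()
  p <- 1L
  repeat {
    cand <- maximal[maximal[, 1] <= p & maximal[, 2] >= p, , drop = FALSE]
    pick <- cand[which.max(cand[, 2]), ]
    chosen[[length(chosen) + 1]] <- pick
    if (pick[2] >= m) break
    p <- pick[2] + 1L
  }
  out <- do.call(rbind, chosen)
  out - 1L  # 0-based (start_idx, end_idx)
}

# --- exhaustive Viterbi oracle ---------------------------------------------

# best path by scoring every one of K^m state sequences
oracle_best_path <- function(logE, log_stay, log_switch) {
  m <- nrow(logE); K <- ncol(logE)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), m)))
  score <- log(1 / K) + logE[cbind(1, paths[, 1])]
  if (m > 1) for (t in 2:m) {
    score <- score + logE[cbind(t, paths[, t])] +
      ifelse(paths[, t] == paths[, t - 1], log_stay, log_switch)
  }
  paths[which.max(score), ]
}

# adjusted Rand index between two labelings (direct from the pair-count
# formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny VCF fixture written on the fly
write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/0\t1/1",
    "chr1\t300\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t1/1\t2/2",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT\t./.\t0/0\t1/1",
    "chr1\t500\t.\tA\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/0"),
    path)
}
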