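# Ground-truthed synthetic panel generator: founder mosaics with
# subspecies-private variants, residual heterozygosity, genotyping error and
# missing data. Emulates an inbred strain panel descended from a small set
# of ancestral founders.

#' Simulation parameters
#'
#' Defaults describe a 50-strain, 500-marker panel over a 2 Mb chromosome
#' built from 8 founders (4 domesticus, 2 musculus, 2 castaneus), with an
#' expected 2 recombination breakpoints per strain, 1% genotyping error,
#' 2% missing data and no residual heterozygosity.
#'
#' @param n_founders number of ancestral founder haplotypes.
#' @param founders_per_subspecies named integer vector summing to
#'   `n_founders`.
#' @param n_strains strains in the emitted panel; the first `n_founders`
#'   strains are pure single-founder genomes (the wild-derived reference
#'   subset), the rest are founder mosaics.
#' @param n_markers biallelic markers, uniformly placed.
#' @param chrom_length_bp chromosome length.
#' @param switch_rate expected breakpoints per mosaic strain (Poisson).
#' @param miss_rate per-call missing probability.
#' @param err_rate per-call allele-flip probability.
#' @param het_region_fraction fraction of the chromosome made heterozygous
#'   in each wild-caught-like strain (the last ceiling(n_strains/10) mosaic
#'   strains); 0 disables het injection.
#' @param private_rate fraction of markers carrying a subspecies-private
#'   variant, per subspecies (guarantees diagnostic SNPs exist).
#' @param seed RNG seed; the simulation is fully reproducible from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_founders = 8,
                       founders_per_subspecies = c(domesticus = 4,
                                                   musculus = 2,
                                                   castaneus = 2),
                       n_strains = 50, n_markers = 500,
                       chrom_length_bp = 2e6, switch_rate = 2,
                       miss_rate = 0.02, err_rate = 0.01,
                       het_region_fraction = 0, private_rate = 0.1,
                       seed = 1) {
  if (sum(founders_per_subspecies) != n_founders)
    stop("founders_per_subspecies must sum to n_founders")
  if (any(founders_per_subspecies < 1))
    stop("every subspecies needs at least one founder")
  rates <- c(miss_rate = miss_rate, err_rate = err_rate,
             het_region_fraction = het_region_fraction,
             private_rate = private_rate)
  if (any(rates < 0 | rates > 1))
    stop("rates must be in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  if (n_strains < n_founders)
    stop("n_strains must be >= n_founders (reference strains are pure)")
  structure(list(n_founders = n_founders,
                 founders_per_subspecies = founders_per_subspecies,
                 n_strains = n_strains, n_markers = n_markers,
                 chrom_length_bp = chrom_length_bp,
                 switch_rate = switch_rate, miss_rate = miss_rate,
                 err_rate = err_rate,
                 het_region_fraction = het_region_fraction,
                 private_rate = private_rate, seed = seed),
            class = "sim_params")
}

#' Simulate a founder-mosaic genotype panel with ground truth
#'
#' Founder haplotypes are independent per-marker biallelic draws plus
#' subspecies-private variants (an allele carried by every founder of one
#' subspecies and no other), guaranteeing fully informative diagnostic SNPs.
#' Each mosaic strain is a piecewise copy of founders with
#' Poisson(switch_rate) breakpoints at uniform positions; heterozygosity is
#' injected into designated wild-caught-like strains, then allele-flip
#' errors and missing calls are applied. Columns are recoded afterwards so
#' code 0 is the major allele.
#'
#' @param params a [sim_params()] object.
#' @return list with `matrix` (a [genotype_matrix()]) and `truth`: a list
#'   with `founder_alleles` (founders x markers, post-recode), `segments`
#'   (data.frame strain/start/end/founder/subspecies in bp),
#'   `marker_founder` (function-free strains x markers founder-id matrix),
#'   `marker_subspecies` (strains x markers), `het_regions`,
#'   `founder_subspecies`, `wild_strains`, `pure_strains`.
#' @export
simulate_panel <- function(params = sim_params()) {
  set.seed(params$seed)
  nf <- params$n_founders
  ns <- params$n_strains
  m <- params$n_markers
  fps <- params$founders_per_subspecies
  founder_sub <- rep(names(fps), fps)
  pos <- sort(sample.int(params$chrom_length_bp, m))
  # founder alleles: background frequency 0.3 for the alternate allele
  fa <- matrix(rbinom(nf * m, 1, 0.3), nrow = nf, ncol = m)
  # subspecies-private variants: disjoint marker sets per subspecies
  priv_n <- round(params$private_rate * m)
  avail <- sample.int(m)
  for (si in seq_along(fps)) {
    take <- avail[seq_len(priv_n)]
    avail <- avail[-seq_len(priv_n)]
    fa[, take] <- 0L
    fa[founder_sub == names(fps)[si], take] <- 1L
  }
  strains <- sprintf("S%03d", seq_len(ns))
  # mosaics: strain i copies founder_of(i); first nf strains are pure
  seg_list <- list()
  marker_founder <- matrix(0L, nrow = ns, ncol = m)
  for (i in seq_len(ns)) {
    if (i <= nf) {
      brk <- numeric(0)
      founders <- i
    } else {
      nb <- rpois(1, params$switch_rate)
      brk <- sort(sample.int(params$chrom_length_bp - 1, nb))
      founders <- integer(nb + 1)
      founders[1] <- sample.int(nf, 1)
      if (nb > 0) for (s in 2:(nb + 1)) {
        # successive segments come from a different founder
        founders[s] <- sample(setdiff(seq_len(nf), founders[s - 1]), 1)
      }
    }
    bounds <- c(0, brk, params$chrom_length_bp)
    for (s in seq_along(founders)) {
      lo <- bounds[s] + 1; hi <- bounds[s + 1]
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        strain = strains[i], start = lo, end = hi,
        founder = founders[s], subspecies = founder_sub[founders[s]],
        stringsAsFactors = FALSE)
      marker_founder[i, pos >= lo & pos <= hi] <- founders[s]
    }
  }
  segments <- do.call(rbind, seg_list)
  calls <- matrix(fa[cbind(as.vector(marker_founder),
                           rep(seq_len(m), each = ns))],
                  nrow = ns, ncol = m)
  storage.mode(calls) <- "integer"
  # residual heterozygosity in the wild-caught-like subset
  wild <- character(0)
  het_regions <- data.frame(strain = character(0), start = integer(0),
                            end = integer(0), stringsAsFactors = FALSE)
  if (params$het_region_fraction > 0) {
    n_wild <- ceiling(ns / 10)
    wild <- strains[(ns - n_wild + 1):ns]
    span <- round(params$het_region_fraction * params$chrom_length_bp)
    for (w in wild) {
      start <- sample.int(params$chrom_length_bp - span, 1)
      het_regions <- rbind(het_regions, data.frame(
        strain = w, start = start, end = start + span - 1,
        stringsAsFactors = FALSE))
      wi <- match(w, strains)
      calls[wi, pos >= start & pos <= start + span - 1] <- 2L
    }
  }
  # genotyping error: flip homozygous calls
  flip <- matrix(runif(ns * m) < params$err_rate, ns, m) &
    (calls == 0L | calls == 1L)
  calls[flip] <- 1L - calls[flip]
  # missing calls
  calls[matrix(runif(ns * m) < params$miss_rate, ns, m)] <- -1L
  # recode so 0 = major allele per column (tie keeps current labeling);
  # keep truth consistent by flipping founder alleles too
  alleles <- matrix(c(rep("A", m), rep("G", m)), ncol = 2)
  for (j in seq_len(m)) {
    n1 <- sum(calls[, j] == 1L); n0 <- sum(calls[, j] == 0L)
    if (n1 > n0) {
      h <- calls[, j] %in% c(0L, 1L)
      calls[h, j] <- 1L - calls[h, j]
      fa[, j] <- 1L - fa[, j]
      alleles[j, ] <- c("G", "A")
    }
  }
  gm <- genotype_matrix(calls, strains, "chr1", pos, alleles)
  marker_sub <- matrix(founder_sub[marker_founder], nrow = ns)
  truth <- list(founder_alleles = fa, segments = segments,
                marker_founder = marker_founder,
                marker_subspecies = marker_sub,
                het_regions = het_regions,
                founder_subspecies = founder_sub,
                wild_strains = wild,
                pure_strains = strains[seq_len(nf)])
  list(matrix = gm, truth = truth)
}

#' Pick a labeled reference subset of pure strains
#'
#' Deterministically selects, by ascending strain index, `k_per_subspecies`
#' strains per subspecies among those whose truth mosaic is a single founder
#' segment.
#'
#' @param truth the `truth` component of [simulate_panel()].
#' @param k_per_subspecies labeled strains requested per subspecies.
#' @return named character vector strain -> subspecies.
#' @export
labeled_reference_subset <- function(truth, k_per_subspecies = 1) {
  seg_counts <- table(truth$segments$strain)
  pure <- names(seg_counts)[seg_counts == 1]
  pure <- pure[order(pure)]
  labels <- character(0)
  for (sub in unique(truth$founder_subspecies)) {
    cand <- pure[vapply(pure, function(s)
      truth$segments$subspecies[truth$segments$strain == s][1] == sub,
      logical(1))]
    if (length(cand) < k_per_subspecies)
      stop("only ", length(cand), " pure ", sub,
           " strain(s) available, need ", k_per_subspecies)
    sel <- cand[seq_len(k_per_subspecies)]
    labels[sel] <- sub
  }
  labels
}
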