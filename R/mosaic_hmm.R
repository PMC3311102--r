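# Diagnostic-SNP calling and Viterbi HMMs for subspecific-origin and
# heterozygosity mosaics.

SUBSPECIES <- c("domesticus", "musculus", "castaneus")

#' HMM parameters
#'
#' @param epsilon emission error rate: probability mass for observing an
#'   allele diagnostic of a different subspecies than the hidden state.
#' @param rho per-marker-step switch rate; stay probability is
#'   1 - (K-1) * rho for a K-state chain, so one fully informative contrary
#'   SNP cannot trigger a switch at the defaults.
#' @param partial_weight log-linear emission weight for partially informative
#'   diagnostic SNPs (fully informative SNPs have weight 1).
#' @param het_emit P(het call | heterozygous state) for the het-block HMM.
#' @param het_err P(het call | inbred state): residual het/typing error.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(epsilon = 0.05, rho = 1e-6, partial_weight = 0.5,
                       het_emit = 0.5, het_err = 0.01) {
  p <- list(epsilon = epsilon, rho = rho, partial_weight = partial_weight,
            het_emit = het_emit, het_err = het_err)
  bad <- names(p)[!vapply(p, function(x) x > 0 && x < 1, logical(1))]
  if (length(bad) > 0)
    stop("HMM parameters must lie in (0, 1): ", paste(bad, collapse = ", "))
  if (1 - 2 * rho <= 0) stop("rho too large: need 1 - 2*rho > 0")
  structure(p, class = "hmm_params")
}

#' Call diagnostic SNPs from subspecies-labeled reference strains
#'
#' An allele is diagnostic for a subspecies when, among the labeled reference
#' strains, it occurs (as a homozygous call) only in strains of that
#' subspecies: fully informative if every labeled strain of the subspecies
#' carries it (weight 1), partially informative otherwise (weight
#' `partial_weight`). Alleles occurring in two or more subspecies, or in
#' none, are not diagnostic.
#'
#' @param gm a [genotype_matrix()].
#' @param labels named character vector strain -> subspecies for the labeled
#'   reference subset; every subspecies must have at least one labeled
#'   strain.
#' @param partial_weight weight assigned to partially informative SNPs.
#' @return data.frame with columns `marker_index` (0-based), `pos`, `chrom`,
#'   `subspecies`, `diagnostic_allele` (0/1), `informativeness`
#'   ("full"/"partial"), `weight`.
#' @export
call_diagnostic_snps <- function(gm, labels, partial_weight = 0.5) {
  subsp <- unique(labels)
  missing_sub <- setdiff(SUBSPECIES, subsp)
  if (length(missing_sub) > 0)
    stop("no labeled strain for subspecies: ",
         paste(missing_sub, collapse = ", "))
  unknown <- setdiff(names(labels), gm$strains)
  if (length(unknown) > 0)
    stop("labeled strain(s) not in panel: ", paste(unknown, collapse = ", "))
  ri <- match(names(labels), gm$strains)
  lab <- as.character(labels)
  out <- vector("list", 2L * n_markers(gm))
  nrec <- 0L
  for (j in seq_len(n_markers(gm))) {
    col <- gm$calls[ri, j]
    for (a in c(0L, 1L)) {
      carriers <- lab[col == a]
      if (length(carriers) == 0L) next
      us <- unique(carriers)
      if (length(us) != 1L) next           # crosses subspecies
      full <- length(carriers) == sum(lab == us)
      nrec <- nrec + 1L
      out[[nrec]] <- data.frame(
        marker_index = j - 1L, pos = gm$pos[j], chrom = gm$chrom[j],
        subspecies = us, diagnostic_allele = a,
        informativeness = if (full) "full" else "partial",
        weight = if (full) 1.0 else partial_weight,
        stringsAsFactors = FALSE)
    }
  }
  if (nrec == 0L)
    return(data.frame(marker_index = integer(0), pos = integer(0),
                      chrom = character(0), subspecies = character(0),
                      diagnostic_allele = integer(0),
                      informativeness = character(0), weight = numeric(0)))
  do.call(rbind, out[seq_len(nrec)])
}

# Log-emission matrix for the subspecies HMM: markers x states. For a call
# matching a state's diagnostic allele, weight * log(1 - eps); matching
# another state's allele, weight * log(eps / 2); het/missing/non-diagnostic
# calls are uninformative (0 in every state).
subspecies_log_emissions <- function(calls, diagnostics, params) {
  mk <- sort(unique(diagnostics$marker_index))
  E <- matrix(0, nrow = length(mk), ncol = length(SUBSPECIES),
              dimnames = list(NULL, SUBSPECIES))
  for (i in seq_along(mk)) {
    d <- diagnostics[diagnostics$marker_index == mk[i], , drop = FALSE]
    call <- calls[i]
    if (!(call %in% c(0L, 1L))) next
    hit <- which(d$diagnostic_allele == call)
    if (length(hit) == 0L) next
    w <- d$weight[hit[1]]
    s <- d$subspecies[hit[1]]
    E[i, ] <- w * log(params$epsilon / 2)
    E[i, s] <- w * log(1 - params$epsilon)
  }
  E
}

# Generic log-space Viterbi with uniform initial distribution and a
# symmetric stay/switch transition structure.
viterbi_path <- function(logE, log_stay, log_switch) {
  m <- nrow(logE); K <- ncol(logE)
  V <- matrix(-Inf, m, K)
  back <- matrix(0L, m, K)
  V[1, ] <- log(1 / K) + logE[1, ]
  if (m > 1) for (t in 2:m) {
    for (k in seq_len(K)) {
      cand <- V[t - 1, ] + ifelse(seq_len(K) == k, log_stay, log_switch)
      back[t, k] <- which.max(cand)
      V[t, k] <- cand[back[t, k]] + logE[t, k]
    }
  }
  path <- integer(m)
  path[m] <- which.max(V[m, ])
  if (m > 1) for (t in (m - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

# Compress a per-marker state path into labeled segments with boundaries at
# midpoints between flanking markers of different states; chromosome ends
# are closed at the first/last marker positions. mean_emission is the mean
# per-marker emission probability of the segment's label.
compress_path <- function(path, pos, chrom, labels, logE, strain) {
  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  seg_start <- seg_end <- integer(k)
  for (i in seq_len(k)) {
    seg_start[i] <- if (i == 1L) pos[1] else
      (pos[starts[i] - 1L] + pos[starts[i]]) %/% 2L + 1L
    seg_end[i] <- if (i == k) pos[length(pos)] else
      (pos[ends[i]] + pos[ends[i] + 1L]) %/% 2L
  }
  data.frame(
    strain = strain, chrom = chrom, start = seg_start, end = seg_end,
    label = labels[runs$values],
    mean_emission = vapply(seq_len(k), function(i)
      mean(exp(logE[starts[i]:ends[i], runs$values[i]])), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Subspecific-origin mosaic via Viterbi HMM
#'
#' Runs a 3-state (domesticus/musculus/castaneus) Viterbi decode for one
#' strain over the diagnostic SNPs, integrating diagnostic strength
#' (log-linear emission weights), an emission error model and a switch
#' penalty that minimizes the number of transitions.
#'
#' @param gm a single-chromosome [genotype_matrix()].
#' @param strain strain name to decode.
#' @param diagnostics diagnostic table from [call_diagnostic_snps()].
#' @param params an [hmm_params()] object.
#' @return data.frame of labeled segments: `strain`, `chrom`, `start`, `end`
#'   (bp, tiling the diagnostic-marker span), `label`, `mean_emission`.
#' @export
subspecies_viterbi <- function(gm, strain, diagnostics, params = hmm_params()) {
  assert_single_chrom(gm)
  if (!strain %in% gm$strains) stop("unknown strain: ", strain)
  if (nrow(diagnostics) == 0L) stop("no diagnostic markers")
  mk <- sort(unique(diagnostics$marker_index))
  calls <- gm$calls[match(strain, gm$strains), mk + 1L]
  informative <- any(calls %in% c(0L, 1L) &
    vapply(seq_along(mk), function(i) {
      d <- diagnostics[diagnostics$marker_index == mk[i], ]
      calls[i] %in% d$diagnostic_allele
    }, logical(1)))
  if (!informative)
    stop("no informative diagnostic calls for strain ", strain)
  logE <- subspecies_log_emissions(calls, diagnostics, params)
  path <- viterbi_path(logE, log(1 - 2 * params$rho), log(params$rho))
  compress_path(path, gm$pos[mk + 1L], gm$chrom[1], SUBSPECIES, logE, strain)
}

#' Heterozygosity blocks via Viterbi HMM
#'
#' 2-state (inbred/heterozygous) Viterbi decode of a strain's het calls:
#' heterozygous calls emit with probability `het_emit` in the heterozygous
#' state and `het_err` in the inbred state (homozygous calls the
#' complements); missing calls are uninformative.
#'
#' @param gm a single-chromosome [genotype_matrix()].
#' @param strain strain name.
#' @param params an [hmm_params()] object.
#' @return data.frame of labeled segments as in [subspecies_viterbi()],
#'   labels in \{"inbred", "heterozygous"\}.
#' @export
heterozygosity_viterbi <- function(gm, strain, params = hmm_params()) {
  assert_single_chrom(gm)
  if (!strain %in% gm$strains) stop("unknown strain: ", strain)
  calls <- gm$calls[match(strain, gm$strains), ]
  obs <- ifelse(calls == 2L, "het", ifelse(calls == -1L, "missing", "hom"))
  if (all(obs == "missing")) stop("all calls missing for strain ", strain)
  logE <- matrix(0, nrow = length(obs), ncol = 2,
                 dimnames = list(NULL, c("inbred", "heterozygous")))
  logE[obs == "het", 1] <- log(params$het_err)
  logE[obs == "het", 2] <- log(params$het_emit)
  logE[obs == "hom", 1] <- log(1 - params$het_err)
  logE[obs == "hom", 2] <- log(1 - params$het_emit)
  path <- viterbi_path(logE, log(1 - params$rho), log(params$rho))
  compress_path(path, gm$pos, gm$chrom[1], c("inbred", "heterozygous"),
                logE, strain)
}
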