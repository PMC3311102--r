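# Core genotype containers and I/O.
#
# Call codes used throughout the package:
#   0 = major allele, 1 = minor allele, 2 = heterozygous, -1 = missing.

CALL_CODES <- c(-1L, 0L, 1L, 2L)

#' Construct a genotype matrix
#'
#' The universal input container: an ordered strain panel genotyped at a set
#' of biallelic SNP markers. Calls are stored as integer codes (0 = major
#' allele, 1 = minor allele, 2 = heterozygous, -1 = missing) with the
#' nucleotide identity of the major/minor alleles kept per marker.
#'
#' @param calls integer matrix, strains x markers, codes in \{-1,0,1,2\}.
#' @param strains character vector of unique strain names (rows of `calls`).
#' @param chrom character vector of chromosome names, one per marker.
#' @param pos integer vector of 1-based base-pair positions, strictly
#'   increasing within each chromosome.
#' @param alleles character matrix, markers x 2, columns `major` and `minor`
#'   nucleotides. Optional; defaults to "A"/"G" placeholders.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, strains, chrom, pos, alleles = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (length(strains) != nrow(calls))
    stop("number of strain names (", length(strains),
         ") does not match rows of calls (", nrow(calls), ")")
  if (anyDuplicated(strains))
    stop("strain names must be unique")
  m <- ncol(calls)
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (length(chrom) != m || length(pos) != m)
    stop("chrom/pos length must equal number of markers")
  if (!all(calls %in% CALL_CODES))
    stop("genotype codes must be in {-1, 0, 1, 2}")
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be >= 1")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(alleles)) {
    alleles <- matrix(c(rep("A", m), rep("G", m)), ncol = 2)
  }
  alleles <- as.matrix(alleles)
  colnames(alleles) <- c("major", "minor")
  rownames(calls) <- strains
  structure(
    list(strains = as.character(strains), chrom = as.character(chrom),
         pos = pos, calls = calls, alleles = alleles),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$strains), "strains x",
      length(x$pos), "markers on",
      length(unique(x$chrom)), "chromosome(s)\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  miss <- mean(x$calls == -1L)
  het <- mean(x$calls == 2L)
  cat(sprintf("  missing %.1f%%, heterozygous %.1f%%\n",
              100 * miss, 100 * het))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

n_markers <- function(x) length(x$pos)

# Single-chromosome guard used by the per-chromosome analyses.
assert_single_chrom <- function(gm) {
  ch <- unique(gm$chrom)
  if (length(ch) != 1L)
    stop("this analysis runs one chromosome at a time; found: ",
         paste(ch, collapse = ", "),
         " (use subset_genotypes with a region first)")
  ch
}

# Map nucleotide/H/N character calls for one marker column to integer codes
# using the major/minor convention: the major allele is the more frequent one
# among non-missing, non-het calls; ties broken toward the lexicographically
# smaller nucleotide.
binarize_column <- function(chars) {
  chars <- toupper(chars)
  code <- rep(-1L, length(chars))
  code[chars == "H"] <- 2L
  nuc <- chars %in% c("A", "C", "G", "T")
  alleles <- sort(unique(chars[nuc]))
  if (length(alleles) > 2L)
    stop("more than two alleles in column: ", paste(alleles, collapse = ","))
  if (length(alleles) == 0L)
    return(list(code = code, major = "N", minor = "N"))
  counts <- vapply(alleles, function(a) sum(chars == a), integer(1))
  # which.max keeps the first (lexicographically smaller) allele on ties
  major <- alleles[which.max(counts)]
  minor <- if (length(alleles) == 2L) setdiff(alleles, major) else major
  code[nuc & chars == major] <- 0L
  code[nuc & chars != major] <- 1L
  list(code = code, major = major, minor = minor)
}

#' Read a genotype matrix
#'
#' Two on-disk formats are supported. `table`: tab-separated, line 1 gives
#' the chromosome of each marker, line 2 the 1-based position, and each
#' subsequent line a strain name followed by one call per marker
#' (A/C/G/T, H = heterozygous, N = missing). `vcf`: a standard VCF; biallelic
#' SNP records are kept, multiallelic records are skipped with a warning,
#' "0/0"-like genotypes map through the major/minor recoding, "0/1" to
#' heterozygous and "./." to missing.
#'
#' @param path path to the input file.
#' @param format `"table"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("table", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "table") read_genotype_table(path) else read_genotype_vcf(path)
}

read_genotype_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L)
    stop("empty or truncated genotype table: need chrom row, pos row and ",
         "at least one strain row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged genotype table: row ", bad, " has ", widths[bad],
         " fields, expected ", widths[1])
  }
  chrom <- fields[[1]][-1]
  pos <- suppressWarnings(as.integer(fields[[2]][-1]))
  if (anyNA(pos)) stop("non-numeric position in header row 2")
  strains <- vapply(fields[-(1:2)], `[`, character(1), 1L)
  raw <- t(vapply(fields[-(1:2)], function(f) f[-1],
                  character(length(chrom))))
  if (length(chrom) == 1L) raw <- matrix(raw, ncol = 1L)
  calls <- matrix(-1L, nrow = length(strains), ncol = length(chrom))
  alleles <- matrix("N", nrow = length(chrom), ncol = 2)
  for (j in seq_along(chrom)) {
    b <- binarize_column(raw[, j])
    calls[, j] <- b$code
    alleles[j, ] <- c(b$major, b$minor)
  }
  for (ch in unique(chrom)) {
    if (is.unsorted(pos[chrom == ch], strictly = TRUE))
      stop("sorting error: positions not strictly increasing on ", ch)
  }
  genotype_matrix(calls, strains, chrom, pos, alleles)
}

read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    warning(n_skip, " multiallelic/non-SNP VCF record(s) skipped")
  if (!any(biallelic)) stop("no biallelic SNP records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  strains <- colnames(gt)
  m <- nrow(gt)
  # decode GT strings into nucleotide-style characters, then binarize so the
  # major/minor convention matches the table reader
  raw <- matrix("N", nrow = length(strains), ncol = m)
  for (j in seq_len(m)) {
    g <- gsub("|", "/", gt[j, ], fixed = TRUE)
    a <- rep("N", length(g))
    a[g %in% c("0/0", "0")] <- fix[j, "REF"]
    a[g %in% c("1/1", "1")] <- fix[j, "ALT"]
    a[g %in% c("0/1", "1/0")] <- "H"
    raw[, j] <- a
  }
  calls <- matrix(-1L, nrow = length(strains), ncol = m)
  alleles <- matrix("N", nrow = m, ncol = 2)
  for (j in seq_len(m)) {
    b <- binarize_column(raw[, j])
    calls[, j] <- b$code
    alleles[j, ] <- c(b$major, b$minor)
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ord <- order(chrom, pos)
  genotype_matrix(calls[, ord, drop = FALSE], strains,
                  chrom[ord], pos[ord], alleles[ord, , drop = FALSE])
}

#' Write a genotype matrix as a genotype table
#'
#' Inverse of the `table` reader: codes are expanded back to nucleotides
#' using the stored major/minor alleles, heterozygous to "H" and missing to
#' "N".
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotype_table <- function(gm, path) {
  m <- n_markers(gm)
  chars <- matrix("N", nrow = length(gm$strains), ncol = m)
  for (j in seq_len(m)) {
    cj <- gm$calls[, j]
    chars[cj == 0L, j] <- gm$alleles[j, 1]
    chars[cj == 1L, j] <- gm$alleles[j, 2]
    chars[cj == 2L, j] <- "H"
  }
  lines <- c(
    paste(c("chrom", gm$chrom), collapse = "\t"),
    paste(c("pos", gm$pos), collapse = "\t"),
    vapply(seq_along(gm$strains), function(i)
      paste(c(gm$strains[i], chars[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(NULL)
}

#' Strain distribution pattern at one marker
#'
#' Returns the binarized allele pattern (SDP) of a marker across the panel:
#' per-strain codes 0 (major), 1 (minor), 2 (het) or -1 (missing).
#'
#' @param gm a [genotype_matrix()].
#' @param marker_index 0-based marker index.
#' @return integer vector of length `n strains`, named by strain.
#' @export
sdp_at <- function(gm, marker_index) {
  m <- n_markers(gm)
  if (marker_index < 0L || marker_index >= m)
    stop("marker index ", marker_index, " out of range [0, ", m - 1, "]")
  gm$calls[, marker_index + 1L]
}

#' Subset a genotype matrix by strains and/or region
#'
#' @param gm a [genotype_matrix()].
#' @param strains strain names to keep, in the requested order. Default: all.
#' @param region optional list/vector with `chrom`, `start`, `end`
#'   (1-based inclusive base pairs); markers with start <= pos <= end on
#'   `chrom` are kept.
#' @return a [genotype_matrix()].
#' @export
subset_genotypes <- function(gm, strains = gm$strains, region = NULL) {
  missing_names <- setdiff(strains, gm$strains)
  if (length(missing_names) > 0)
    stop("unknown strain name(s): ", paste(missing_names, collapse = ", "))
  ri <- match(strains, gm$strains)
  if (is.null(region)) {
    keep <- seq_len(n_markers(gm))
  } else {
    region <- as.list(region)
    keep <- which(gm$chrom == region$chrom &
                  gm$pos >= as.integer(region$start) &
                  gm$pos <= as.integer(region$end))
  }
  genotype_matrix(gm$calls[ri, keep, drop = FALSE], strains,
                  gm$chrom[keep], gm$pos[keep],
                  gm$alleles[keep, , drop = FALSE])
}

#' Write labeled genomic intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' start becomes start-1 and end is unchanged. The optional `score` column
#' fills BED column 5.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`, `name`
#'   and optionally `score`.
#' @param path output path.
#' @export
write_intervals_bed <- function(intervals, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  if (nrow(intervals) > 0) {
    score <- if ("score" %in% names(intervals)) intervals$score else 0L
    lines <- paste(intervals$chrom,
                   as.integer(intervals$start) - 1L,
                   as.integer(intervals$end),
                   intervals$name, score, sep = "\t")
    writeLines(lines, con)
  }
  invisible(NULL)
}

#' Read a strain metadata table
#'
#' Tab-separated with header: columns `strain`, `class` (classical,
#' wild_derived or wild_caught) and `subspecies` (blank if unknown).
#'
#' @param path input path.
#' @return data.frame with those columns.
#' @export
read_strain_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "class", "subspecies")
  if (!all(need %in% names(df)))
    stop("strain metadata must have columns: ", paste(need, collapse = ", "))
  df
}
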