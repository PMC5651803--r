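# Read-level characterization: canonical k-mer histograms, genome-size
# estimation from the k-mer coverage peak, per-read GC distributions, and
# the picogram/base-pair and coverage-ratio utilities.

#' Canonical k-mer frequency histogram
#'
#' Counts canonical k-mers (the lexicographic minimum of each k-mer and
#' its reverse complement) over a read set and tabulates how many distinct
#' canonical k-mers occur at each multiplicity. K-mers containing `N` are
#' skipped. The histogram is invariant under reverse-complementing any
#' subset of the reads.
#'
#' @param reads Character vector of read sequences, or a FASTA/FASTQ path.
#' @param k Odd word size in `[3, 31]` (default 21; genome-scale counting
#'   normally uses 11-31, small values are allowed for toy inputs).
#' @return Object of class `kmer_histogram`: `k`, `counts` (data frame
#'   `multiplicity`, `n_kmers`), `total_kmers`.
#' @export
kmer_histogram <- function(reads, k = 21L) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_reads(reads)
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 3L || k > 31L)
    stop("k must be odd and in [3, 31]", call. = FALSE)
  lens <- nchar(reads)
  if (any(k > lens)) stop("k exceeds a read length", call. = FALSE)
  per_read <- lapply(reads, function(r) {
    n <- nchar(r)
    fwd <- substring(r, 1:(n - k + 1L), k:n)
    rc <- revcomp(r)
    bwd <- rev(substring(rc, 1:(n - k + 1L), k:n))  # bwd[i] = revcomp(fwd[i])
    canon <- pmin(fwd, bwd)
    canon[!grepl("N", fwd, fixed = TRUE)]
  })
  kmers <- unlist(per_read, use.names = FALSE)
  mult <- table(kmers)
  hist <- table(as.integer(mult))
  counts <- data.frame(multiplicity = as.integer(names(hist)),
                       n_kmers = as.integer(hist))
  structure(list(k = k, counts = counts,
                 total_kmers = length(kmers)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("<kmer_histogram> k=%d, %d total k-mers, %d distinct\n",
              x$k, x$total_kmers, sum(x$counts$n_kmers)))
  invisible(x)
}

#' Estimate genome size from a k-mer histogram
#'
#' Finds the largest local maximum of the (3-bin smoothed) histogram at
#' multiplicity `>= min_multiplicity`, excluding the initial low-copy
#' slope; the genome size is `total_kmers / peak_multiplicity`. A
#' monotonically decreasing histogram — the signature of a genome too
#' large or repeat-rich for the available coverage — yields status
#' `"no_nontrivial_maximum"` and no size.
#'
#' @param hist A [kmer_histogram()].
#' @param min_multiplicity Lowest multiplicity a peak may sit at.
#' @return Object of class `genome_size_estimate`: `status`
#'   (`"estimated"` or `"no_nontrivial_maximum"`), `peak_multiplicity`,
#'   `size_bp` (both `NA` when not estimated), `total_kmers`.
#' @export
estimate_genome_size <- function(hist, min_multiplicity = 4L) {
  ct <- hist$counts
  if (!nrow(ct)) stop("empty histogram", call. = FALSE)
  maxm <- max(ct$multiplicity)
  dense <- numeric(maxm)
  dense[ct$multiplicity] <- ct$n_kmers
  sm <- if (maxm >= 3L)
    stats::filter(dense, rep(1 / 3, 3), sides = 2)
  else dense
  sm[is.na(sm)] <- dense[is.na(sm)]
  interior <- which(seq_len(maxm) >= max(2L, min_multiplicity) &
                    seq_len(maxm) < maxm)
  is_peak <- vapply(interior, function(i)
    sm[i] > sm[i - 1L] && sm[i] >= sm[i + 1L] && dense[i] > 0, TRUE)
  peaks <- interior[is_peak]
  if (!length(peaks))
    return(structure(list(status = "no_nontrivial_maximum",
                          peak_multiplicity = NA_integer_,
                          size_bp = NA_real_,
                          total_kmers = hist$total_kmers),
                     class = "genome_size_estimate"))
  peak <- peaks[which.max(sm[peaks])]
  structure(list(status = "estimated",
                 peak_multiplicity = as.integer(peak),
                 size_bp = hist$total_kmers / peak,
                 total_kmers = hist$total_kmers),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  if (x$status == "estimated")
    cat(sprintf("<genome_size_estimate> %.0f bp (peak multiplicity %d)\n",
                x$size_bp, x$peak_multiplicity))
  else cat("<genome_size_estimate> no non-trivial maximum\n")
  invisible(x)
}

#' Per-read GC-content distribution
#'
#' GC fraction per read (N excluded), binned and normalized to relative
#' frequencies.
#'
#' @param reads Character vector of read sequences, or a FASTA/FASTQ path.
#' @param bins Number of equal-width bins over `[0, 1]` (default 50).
#' @return Data frame: `gc_mid` (bin center), `freq` (sums to 1).
#' @export
read_gc_distribution <- function(reads, bins = 50L) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_reads(reads)
  if (!length(reads)) stop("no reads", call. = FALSE)
  gc <- vapply(reads, function(r) {
    n <- .base_counts(r)
    tot <- n[["A"]] + n[["C"]] + n[["G"]] + n[["T"]]
    if (tot == 0) NA_real_ else (n[["G"]] + n[["C"]]) / tot
  }, 0, USE.NAMES = FALSE)
  gc <- gc[!is.na(gc)]
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(findInterval(gc, breaks), bins)
  cnt <- tabulate(idx, nbins = bins)
  data.frame(gc_mid = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
             freq = cnt / sum(cnt))
}

#' Convert a DNA mass in picograms to base pairs
#'
#' Uses the standard conversion 1 pg = 0.978 x 10^9 bp of double-stranded
#' DNA.
#'
#' @param picograms Non-negative DNA mass in pg.
#' @return Base pairs.
#' @export
pg_to_bp <- function(picograms) {
  if (any(picograms < 0)) stop("mass must be non-negative", call. = FALSE)
  picograms * 0.978e9
}

#' Coverage ratio between two loci or samples
#'
#' @param mean_cov_A,mean_cov_B Positive mean coverages.
#' @return List: `ratio` (raw) and `rounded` (1 decimal).
#' @export
coverage_ratio <- function(mean_cov_A, mean_cov_B) {
  if (mean_cov_A <= 0 || mean_cov_B <= 0)
    stop("coverages must be positive", call. = FALSE)
  r <- mean_cov_A / mean_cov_B
  list(ratio = r, rounded = round(r, 1))
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path File path; format detected from the first character.
#' @return Character vector of sequences, named by read id.
#' @export
read_reads <- function(path) {
  first <- readChar(path, 1L)
  set <- Biostrings::readBStringSet(path,
                                    format = if (first == "@") "fastq"
                                             else "fasta")
  out <- toupper(as.character(set))
  names(out) <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  out
}
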