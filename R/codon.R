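# Codon-level accounting under the invertebrate mitochondrial code:
# incomplete stop codons, amino-acid chain-length bookkeeping, four-fold
# degenerate (neutral) sites, and relative standard deviations.

#' Classify the stop codon of a coding sequence
#'
#' Mitochondrial CDS frequently end in an incomplete stop codon (`T` or
#' `TA`) that is completed to `TAA` by transcript polyadenylation; this is
#' detected from the length modulo 3 together with the trailing bases.
#'
#' @param cds_seq In-frame coding sequence (length >= 3).
#' @return `"complete"`, `"partial_TA"`, `"partial_T"` or `"no_stop"`.
#' @export
classify_stop <- function(cds_seq) {
  n <- nchar(cds_seq)
  if (n < 3L) stop("CDS shorter than one codon", call. = FALSE)
  r <- n %% 3L
  if (r == 0L) {
    if (substr(cds_seq, n - 2L, n) %in% c("TAA", "TAG")) "complete"
    else "no_stop"
  } else if (r == 2L) {
    if (substr(cds_seq, n - 1L, n) == "TA") "partial_TA" else "no_stop"
  } else {
    if (substr(cds_seq, n, n) == "T") "partial_T" else "no_stop"
  }
}

#' Amino-acid chain length from nucleotide length
#'
#' For a complete stop codon the chain length is `nt/3 - 1`; for an
#' incomplete (`partial_T`, `partial_TA`) stop every full codon codes, so
#' the chain length is `floor(nt/3)`. Vectorised over both arguments.
#'
#' @param nt_length Nucleotide length(s), each >= 3.
#' @param stop_status `"complete"`, `"partial_TA"`, `"partial_T"` or
#'   `"no_stop"` (the last treated like an incomplete stop: all codons code).
#' @return Integer residue count(s).
#' @export
aa_chain_length <- function(nt_length, stop_status) {
  nt_length <- as.integer(nt_length)
  n <- length(nt_length)
  stop_status <- rep_len(stop_status, n)
  out <- integer(n)
  for (i in seq_len(n)) {
    nt <- nt_length[i]
    if (nt < 3L) stop("nt_length must be >= 3", call. = FALSE)
    if (stop_status[i] == "complete") {
      if (nt %% 3L != 0L)
        stop("complete stop with length not divisible by 3: ", nt,
             call. = FALSE)
      out[i] <- nt %/% 3L - 1L
    } else {
      out[i] <- nt %/% 3L
    }
  }
  out
}

#' Infer stop status from nucleotide length alone
#'
#' Length mod 3 identifies incomplete stops when only printed lengths are
#' available: remainder 2 implies a `TA` trailing stop fragment, remainder
#' 1 a `T`; divisible lengths are taken as complete.
#'
#' @param nt_length Nucleotide length(s).
#' @return Character vector of stop statuses.
#' @export
stop_status_from_length <- function(nt_length) {
  c("complete", "partial_T", "partial_TA")[nt_length %% 3L + 1L]
}

# four-fold degenerate codon families (first two bases) under a code table
.fourfold_families <- function(code = mito_code()) {
  pre <- unique(substr(names(code), 1L, 2L))
  pre[vapply(pre, function(p) {
    aas <- code[paste0(p, c("A", "C", "G", "T"))]
    !any(aas == "*") && length(unique(aas)) == 1L
  }, TRUE)]
}

#' Four-fold degenerate third-codon positions
#'
#' A third position is four-fold degenerate when the codon's first two
#' bases define a family whose four completions encode one amino acid.
#' Under the invertebrate mitochondrial code these families are TCN, CTN,
#' CCN, CGN, ACN, GTN, GCN, GGN and AGN (AGA/AGG = Ser makes AGN
#' four-fold).
#'
#' @param cds_seq In-frame sense-strand coding sequence.
#' @param code Codon map from [mito_code()].
#' @return List of class `neutral_sites`: `positions` (0-based indices,
#'   all `== 2 (mod 3)`) and `counts` (A/C/G/T tallies at those sites).
#' @export
fourfold_positions <- function(cds_seq, code = mito_code()) {
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) {
    warning("trailing partial codon ignored")
    n <- n - n %% 3L
  }
  starts <- seq.int(1L, n - 2L, by = 3L)
  pre2 <- substring(cds_seq, starts, starts + 1L)
  third <- substring(cds_seq, starts + 2L, starts + 2L)
  keep <- pre2 %in% .fourfold_families(code)
  pos0 <- starts[keep] + 1L            # 0-based third positions
  bases <- third[keep]
  structure(list(
    positions = pos0,
    counts = c(A = sum(bases == "A"), C = sum(bases == "C"),
               G = sum(bases == "G"), T = sum(bases == "T"))
  ), class = "neutral_sites")
}

#' GC skew at four-fold degenerate sites of a gene
#'
#' Computes the GC skew over the neutral (four-fold degenerate) third
#' positions of a CDS, read on its own sense strand (native direction).
#' For a minus-strand gene this equals minus the skew of the complementary
#' bases read on the genome's forward strand.
#'
#' @param genome A [mito_genome()].
#' @param feature CDS feature row.
#' @param code Codon map from [mito_code()].
#' @return Skew value, or `NA` when the neutral sites carry no G or C.
#' @export
neutral_site_gc_skew <- function(genome, feature, code = mito_code()) {
  if (feature$kind != "CDS") stop("feature is not a CDS", call. = FALSE)
  s <- extract_gene_seq(genome, feature)
  ns <- suppressWarnings(fourfold_positions(s, code))
  d <- ns$counts[["G"]] + ns$counts[["C"]]
  if (d == 0) NA_real_ else (ns$counts[["G"]] - ns$counts[["C"]]) / d
}

# round half away from zero (printed-table convention)
.round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Relative standard deviation of ortholog lengths
#'
#' Sample standard deviation (n-1 denominator) divided by the mean, as a
#' percentage, rounded half-up to 2 decimals — the convention of printed
#' ortholog-length tables.
#'
#' @param lengths Numeric vector (>= 2 values).
#' @return RSD percent (2 decimals).
#' @export
ortholog_rsd <- function(lengths) {
  if (length(lengths) < 2L) stop("need at least 2 values", call. = FALSE)
  .round_half_up(stats::sd(lengths) / mean(lengths) * 100, 2L)
}

#' Count CDS with incomplete stop codons
#'
#' @param table Data frame with an `nt_length` (or `bp`) column.
#' @return Number of records whose length is not divisible by 3.
#' @export
incomplete_stop_census <- function(table) {
  bp <- if ("nt_length" %in% names(table)) table$nt_length else table$bp
  sum(bp %% 3L != 0L)
}

#' Printed protein-coding gene lengths of four Calanus species
#'
#' The published nucleotide lengths (bp) and amino-acid chain lengths (aa)
#' of the 13 mitochondrial protein-coding genes of *C. glacialis*,
#' *C. finmarchicus*, *C. hyperboreus* and *C. sinicus*. These printed
#' values are inputs for the chain-length accounting checks; `aa_printed`
#' carries the published chain lengths for cross-validation.
#'
#' @return Long data frame: `gene`, `species`, `bp`, `aa_printed`.
#' @export
calanus_cds_table <- function() {
  genes <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb", "nd1",
             "nd2", "nd3", "nd4", "nd4l", "nd5", "nd6")
  bp <- list(
    glacialis    = c(714, 162, 1557, 705, 792, 1133, 919, 969, 354, 1302, 336, 1711, 474),
    finmarchicus = c(712, 162, 1557, 705, 792, 1132, 919, 969, 354, 1302, 336, 1712, 483),
    hyperboreus  = c(708, 159, 1546, 704, 792, 1137, 915, 969, 354, 1302, 336, 1710, 474),
    sinicus      = c(711, 162, 1548, 705, 792, 1137, 917, 969, 354, 1302, 336, 1723, 480))
  aa <- list(
    glacialis    = c(237, 53, 518, 234, 263, 377, 306, 322, 117, 433, 111, 570, 157),
    finmarchicus = c(237, 53, 518, 234, 263, 377, 306, 322, 117, 433, 111, 570, 160),
    hyperboreus  = c(235, 52, 515, 234, 263, 378, 304, 322, 117, 433, 111, 569, 157),
    sinicus      = c(236, 53, 515, 234, 263, 378, 305, 322, 117, 433, 111, 574, 159))
  do.call(rbind, lapply(names(bp), function(sp)
    data.frame(gene = genes, species = sp, bp = as.integer(bp[[sp]]),
               aa_printed = as.integer(aa[[sp]]), stringsAsFactors = FALSE)))
}

#' Published contig lengths of the two sequenced mitogenomes
#'
#' @return Named list of integer vectors of assembled contig lengths (bp).
#' @export
calanus_contig_lengths <- function() {
  list(glacialis = c(9686L, 17656L),
       finmarchicus = c(1431L, 17682L, 4129L, 1417L, 2074L, 2729L))
}
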