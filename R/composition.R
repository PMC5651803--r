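# Compositional statistics: skews, sliding windows, strand asymmetry.
# Skews are undefined (NA) when the denominator is zero; NA is a marker,
# never silently coerced to 0. N bases are excluded from every count.

#' AT skew
#'
#' `(A - T) / (A + T)` counting only A and T.
#'
#' @param seq DNA string.
#' @return Value in `[-1, 1]`, or `NA` when `A + T == 0`.
#' @export
at_skew <- function(seq) {
  n <- .base_counts(seq)
  d <- n[["A"]] + n[["T"]]
  if (d == 0) NA_real_ else (n[["A"]] - n[["T"]]) / d
}

#' GC skew
#'
#' `(G - C) / (G + C)` counting only G and C. Reverse-complementing a
#' sequence flips the sign.
#'
#' @inheritParams at_skew
#' @return Value in `[-1, 1]`, or `NA` when `G + C == 0`.
#' @export
gc_skew <- function(seq) {
  n <- .base_counts(seq)
  d <- n[["G"]] + n[["C"]]
  if (d == 0) NA_real_ else (n[["G"]] - n[["C"]]) / d
}

#' Window specification for sliding statistics
#'
#' @param width Window width in bp (default 300).
#' @param step Step in bp.
#' @param wrap Let windows cross the origin (circular contigs).
#' @return A `window_spec` list.
#' @export
window_spec <- function(width = 300L, step = 10L, wrap = FALSE) {
  width <- as.integer(width); step <- as.integer(step)
  stopifnot(width >= 1L, step >= 1L)
  structure(list(width = width, step = step, wrap = isTRUE(wrap)),
            class = "window_spec")
}

#' Sliding-window composition profile
#'
#' Windows are anchored at position 0 and advance by `spec$step`. On a
#' wrapped (circular) profile there are `ceiling(L / step)` windows and
#' windows cross the origin; on a linear profile there are
#' `floor((L - width) / step) + 1`. Centers are reported in 0-based contig
#' coordinates. N bases are excluded from all counts.
#'
#' @param ct A [contig()] (or DNA string, treated as linear).
#' @param spec A [window_spec()]; `wrap` is forced off for linear contigs.
#' @return Data frame of class `skew_profile` with columns `contig`,
#'   `center`, `at_skew`, `gc_skew`, `gc_content`.
#' @export
sliding_composition <- function(ct, spec = window_spec()) {
  if (is.character(ct)) ct <- contig("seq", ct)
  seq <- ct$seq
  L <- nchar(seq)
  wrap <- spec$wrap && ct$circular
  if (!wrap && spec$width > L)
    stop("window width exceeds linear contig length", call. = FALSE)
  # cumulative counts give O(1) per-window counts
  ext <- if (wrap) paste0(seq, substr(seq, 1L, spec$width)) else seq
  ch <- strsplit(ext, "", fixed = TRUE)[[1]]
  cum <- function(b) c(0L, cumsum(ch == b))
  cA <- cum("A"); cC <- cum("C"); cG <- cum("G"); cT <- cum("T")
  starts <- if (wrap) seq.int(0L, L - 1L, by = spec$step)
            else seq.int(0L, L - spec$width, by = spec$step)
  ends <- starts + spec$width
  n <- function(cm) cm[ends + 1L] - cm[starts + 1L]
  A <- n(cA); C <- n(cC); G <- n(cG); T <- n(cT)
  atd <- A + T; gcd <- G + C; tot <- atd + gcd
  data.frame(
    contig = ct$id,
    center = (starts + spec$width / 2) %% if (wrap) L else Inf,
    at_skew = ifelse(atd == 0, NA_real_, (A - T) / atd),
    gc_skew = ifelse(gcd == 0, NA_real_, (G - C) / gcd),
    gc_content = ifelse(tot == 0, NA_real_, gcd / tot),
    stringsAsFactors = FALSE
  ) -> prof
  class(prof) <- c("skew_profile", "data.frame")
  prof
}

#' Whole-genome base composition summary
#'
#' Percentages over all contigs concatenated, N excluded. The "heavy"
#' strand is defined operationally as the strand with the larger G+T
#' content (ties resolved to the forward strand).
#'
#' @param genome A [mito_genome()], [contig()], or DNA string.
#' @return List: `length`, `n_count`, `at_percent`, `gc_percent`,
#'   `gt_percent_forward`, `gt_percent_reverse`, `heavy_strand`
#'   (`"forward"`/`"reverse"`), `heavy_gt_percent`.
#' @export
base_summary <- function(genome) {
  seqs <- if (inherits(genome, "mito_genome"))
    vapply(genome$contigs, `[[`, "", "seq")
  else if (inherits(genome, "contig")) genome$seq
  else genome
  n <- Reduce(`+`, lapply(seqs, .base_counts))
  tot <- n[["A"]] + n[["C"]] + n[["G"]] + n[["T"]]
  if (tot == 0) stop("no unambiguous bases", call. = FALSE)
  # reverse strand: G+T there = C+A here
  gt_f <- (n[["G"]] + n[["T"]]) / tot * 100
  gt_r <- (n[["C"]] + n[["A"]]) / tot * 100
  list(
    length = sum(nchar(seqs)),
    n_count = n[["N"]],
    at_percent = (n[["A"]] + n[["T"]]) / tot * 100,
    gc_percent = (n[["G"]] + n[["C"]]) / tot * 100,
    gt_percent_forward = gt_f,
    gt_percent_reverse = gt_r,
    heavy_strand = if (gt_f >= gt_r) "forward" else "reverse",
    heavy_gt_percent = max(gt_f, gt_r)
  )
}

# average residue masses of the deoxyribonucleoside monophosphates (g/mol)
.DNMP_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)

#' Relative molecular-weight difference between the two DNA strands
#'
#' Per-strand weight is the sum of average residue masses (dAMP 313.21,
#' dCMP 289.18, dGMP 329.21, dTMP 304.20 g/mol); the result is
#' `|W1 - W2| / mean(W1, W2) * 100`. The value is invariant under sequence
#' rotation and zero for self-reverse-complementary sequences.
#'
#' @param seq DNA string; N bases are excluded with a warning.
#' @param masses Named residue-mass vector (A, C, G, T), overridable.
#' @return Percent difference.
#' @export
strand_weight_diff <- function(seq, masses = .DNMP_MASS) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  n <- .base_counts(seq)
  if (n[["N"]] > 0) warning("N bases excluded from strand weights")
  b <- n[c("A", "C", "G", "T")]
  if (sum(b) == 0) stop("no unambiguous bases", call. = FALSE)
  w1 <- sum(b * masses[c("A", "C", "G", "T")])
  # complement strand has the complementary base counts
  w2 <- sum(b * masses[c("T", "G", "C", "A")])
  abs(w1 - w2) / mean(c(w1, w2)) * 100
}

#' Write a skew profile as TSV
#'
#' @param profile A `skew_profile` from [sliding_composition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
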