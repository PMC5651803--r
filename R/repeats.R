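# Non-coding-region profiling: tandem microsatellite-like arrays, inverted
# terminal repeats (palindromes), and word-based dotplot match extraction.

# lexicographically smallest rotation of a repeat unit
.canonical_rotation <- function(unit) {
  n <- nchar(unit)
  if (n == 1L) return(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1L, i - 1L)), "")
  min(rots)
}

#' Find tandem repeat arrays
#'
#' Reports maximal, non-extendable tandem arrays with unit length up to
#' `max_unit` and at least `min_copies` copies. Units are reported in
#' canonical rotation (lexicographically smallest), so the same locus is
#' never reported twice under rotated units; arrays whose unit is a whole
#' multiple of an already-reported shorter unit at the same locus are
#' merged into the shorter-unit report. A fractional trailing copy counts
#' when it covers at least half a unit; otherwise the array is trimmed to
#' whole copies.
#'
#' @param seq DNA string (or [contig()]).
#' @param max_unit Maximum unit length (default 6).
#' @param min_copies Minimum copy number (default 3).
#' @return Data frame: `start`, `end` (0-based half-open), `unit`
#'   (canonical rotation), `copies` (possibly fractional).
#' @export
find_tandem_arrays <- function(seq, max_unit = 6L, min_copies = 3) {
  if (inherits(seq, "contig")) seq <- seq$seq
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  out <- list()
  for (u in seq_len(min(max_unit, max(1L, L %/% 2L)))) {
    if (L < 2L * u) break
    eq <- ch[seq_len(L - u)] == ch[(u + 1L):L]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (k in which(r$values & r$lengths >= u * (min_copies - 1))) {
      s <- pos[k]                        # 1-based start of the equal run
      span <- r$lengths[k] + u           # maximal period-u span in bp
      full <- span %/% u
      fracbp <- span - full * u
      if (fracbp >= u / 2) copies <- full + fracbp / u
      else { copies <- full; span <- full * u }
      if (copies < min_copies) next
      start0 <- s - 1L
      # merge: skip if covered by a shorter-unit array whose unit divides u
      covered <- FALSE
      for (a in out) {
        if (u %% nchar(a$unit) == 0L && start0 >= a$start &&
            start0 + span <= a$end) { covered <- TRUE; break }
      }
      if (covered) next
      out[[length(out) + 1L]] <- list(
        start = start0, end = start0 + as.integer(span),
        unit = .canonical_rotation(substr(seq, s, s + u - 1L)),
        copies = copies)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), copies = numeric(0)))
  df <- do.call(rbind, lapply(out, as.data.frame))
  df[order(df$start, df$end), , drop = FALSE]
}

# word-match pairs of A against B in one orientation, merged into maximal
# diagonal runs; coordinates 0-based word starts
.word_matches <- function(seqA, seqB, word, reverse = FALSE) {
  nA <- nchar(seqA); nB <- nchar(seqB)
  if (nA < word || nB < word)
    return(data.frame(posA = integer(0), posB = integer(0),
                      length = integer(0)))
  wA <- substring(seqA, 1:(nA - word + 1L), word:nA)
  bsrc <- if (reverse) revcomp(seqB) else seqB
  wB <- substring(bsrc, 1:(nB - word + 1L), word:nB)
  idxB <- split(seq_along(wB), wB)
  hits <- idxB[wA]
  ni <- lengths(hits)
  if (sum(ni) == 0L)
    return(data.frame(posA = integer(0), posB = integer(0),
                      length = integer(0)))
  ia <- rep.int(seq_along(wA), ni)      # 1-based word starts in A
  ib <- unlist(hits, use.names = FALSE) # 1-based in bsrc
  if (reverse) ib <- nB - word + 2L - ib  # map back to forward B coords
  # merge runs along diagonals: forward diag = ia - ib; reverse anti = ia + ib
  d <- if (reverse) ia + ib else ia - ib
  o <- order(d, ia)
  ia <- ia[o]; ib <- ib[o]; d <- d[o]
  new_run <- c(TRUE, d[-1] != d[-length(d)] | diff(ia) != 1L)
  run_id <- cumsum(new_run)
  firstA <- tapply(ia, run_id, min)
  lens <- tabulate(run_id) + word - 1L
  posB <- if (reverse) tapply(ib, run_id, min) else tapply(ib, run_id, min)
  data.frame(posA = as.integer(firstA) - 1L,
             posB = as.integer(posB) - 1L,
             length = as.integer(lens))
}

#' Exact dotplot matches between two sequences
#'
#' All exact word matches in forward and reverse-complement orientation,
#' merged into maximal diagonals. For a reverse match, `posA`/`posB` give
#' the 0-based starts of the matching segments on the forward strands of
#' the two sequences.
#'
#' @param seqA,seqB DNA strings (or [contig()]s).
#' @param word Word size (>= 4; default 11).
#' @param step Word sampling step in A (default 1; kept at 1 for maximal
#'   merging).
#' @return Data frame of class `dotplot_matches`: `posA`, `posB`,
#'   `length`, `orientation`.
#' @export
dotplot_matches <- function(seqA, seqB, word = 11L, step = 1L) {
  if (inherits(seqA, "contig")) seqA <- seqA$seq
  if (inherits(seqB, "contig")) seqB <- seqB$seq
  if (word < 4L) stop("word size must be >= 4", call. = FALSE)
  fw <- .word_matches(seqA, seqB, word, reverse = FALSE)
  rv <- .word_matches(seqA, seqB, word, reverse = TRUE)
  fw$orientation <- rep("forward", nrow(fw))
  rv$orientation <- rep("reverse", nrow(rv))
  out <- rbind(fw, rv)
  out <- out[order(out$posA, out$posB), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dotplot_matches", "data.frame")
  out
}

#' Find inverted repeats in contig terminal windows
#'
#' Looks for maximal substrings within each terminal window of a contig
#' that match the reverse complement of another substring of the same
#' window — the palindromic (inverted-repeat) signature of fragmented
#' mitochondrial chromosome ends. Matching is exact; runs on the same
#' anti-diagonal separated by at most `max_mismatch` positions are joined.
#'
#' @param ct A [contig()] (or DNA string).
#' @param window Terminal window size (default 500).
#' @param min_len Minimum repeat arm length (default 10).
#' @param max_mismatch Mismatches tolerated when joining runs (default 0).
#' @return Data frame: `end` (`"start"`/`"end"` of the contig), `posA`,
#'   `posB` (0-based contig coordinates of the two arms), `length`.
#' @export
find_terminal_palindromes <- function(ct, window = 500L, min_len = 10L,
                                      max_mismatch = 0L) {
  if (inherits(ct, "contig")) ct <- ct$seq
  L <- nchar(ct)
  if (L < window) stop("contig shorter than terminal window", call. = FALSE)
  if (min_len > window)
    return(data.frame(end = character(0), posA = integer(0),
                      posB = integer(0), length = integer(0)))
  scan_window <- function(sub, offset, label) {
    m <- .word_matches(sub, sub, word = min_len, reverse = TRUE)
    if (!nrow(m)) return(NULL)
    if (max_mismatch > 0L && nrow(m) > 1L) {
      # join runs on the same anti-diagonal across small mismatch gaps
      anti <- m$posA + m$posB + m$length
      o <- order(anti, m$posA)
      m <- m[o, ]; anti <- anti[o]
      i <- 1L
      while (i < nrow(m)) {
        gap <- m$posA[i + 1L] - (m$posA[i] + m$length[i])
        if (anti[i + 1L] == anti[i] && gap >= 1L && gap <= max_mismatch) {
          m$length[i] <- m$posA[i + 1L] + m$length[i + 1L] - m$posA[i]
          m$posB[i] <- m$posB[i + 1L]
          m <- m[-(i + 1L), ]; anti <- anti[-(i + 1L)]
        } else i <- i + 1L
      }
    }
    m <- m[m$posA < m$posB, , drop = FALSE]   # dedupe symmetric pairs
    if (!nrow(m)) return(NULL)
    data.frame(end = label, posA = m$posA + offset, posB = m$posB + offset,
               length = m$length)
  }
  out <- rbind(
    scan_window(substr(ct, 1L, window), 0L, "start"),
    scan_window(substr(ct, L - window + 1L, L), L - window, "end"))
  if (is.null(out))
    out <- data.frame(end = character(0), posA = integer(0),
                      posB = integer(0), length = integer(0))
  rownames(out) <- NULL
  out
}
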