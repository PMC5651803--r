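# Uncorrected p-distances with complete deletion and site bootstrap, a
# linear-gap Needleman-Wunsch aligner as plumbing, gene concatenation and
# sliding-window distances.

# run code with a private RNG stream; global .Random.seed untouched
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Construct an alignment block
#'
#' Equal-length aligned rows over a residue alphabet plus `-` (gap) and
#' `?` (missing).
#'
#' @param rows Named character vector of aligned sequences (or a character
#'   matrix with one row per sequence).
#' @return Object of class `alignment_block`: `labels`, `mat` (character
#'   matrix, sequences x columns), `kept_columns` (original column indices
#'   still present; initially all).
#' @export
alignment_block <- function(rows) {
  if (is.matrix(rows)) {
    mat <- rows
    labels <- rownames(mat)
  } else {
    if (length(unique(nchar(rows))) != 1L)
      stop("aligned rows must have equal length", call. = FALSE)
    labels <- names(rows)
    mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  }
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(mat)))
  rownames(mat) <- labels
  structure(list(labels = labels, mat = mat,
                 kept_columns = seq_len(ncol(mat))),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block> %d sequence(s) x %d column(s)\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Global pairwise alignment (Needleman-Wunsch, linear gaps)
#'
#' Optimal global alignment under match/mismatch scores and a linear gap
#' penalty. Traceback tie-breaking is deterministic: diagonal is preferred
#' over a gap in the second sequence (up), which is preferred over a gap in
#' the first (left).
#'
#' @param seqA,seqB Non-empty residue strings (nt or aa).
#' @param match,mismatch,gap Scores (gap per residue, linear).
#' @return An [alignment_block()] with rows `A`, `B` and attribute `score`.
#' @export
global_align <- function(seqA, seqB, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(seqA, "", fixed = TRUE)[[1]]
  b <- strsplit(seqB, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("empty sequence", call. = FALSE)
  H <- matrix(0, n + 1L, m + 1L)
  H[1, ] <- gap * (0:m)
  H[, 1] <- gap * (0:n)
  jj <- seq_len(m)
  for (i in seq_len(n)) {
    s <- ifelse(b == a[i], match, mismatch)
    prev <- H[i, ]
    V <- pmax(prev[jj] + s, prev[jj + 1L] + gap)    # diag, up
    # left moves folded in as a running max: H[i,j] = gap*j + cummax(V - gap*j)
    u <- cummax(c(gap * i, V - gap * jj))
    H[i + 1L, 1L] <- gap * i
    H[i + 1L, jj + 1L] <- gap * jj + u[-1L]
  }
  # traceback (prefer diagonal, then up, then left)
  i <- n; j <- m
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        H[i + 1L, j + 1L] ==
          H[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      ra <- c(a[i], ra); rb <- c(b[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && H[i + 1L, j + 1L] == H[i, j + 1L] + gap) {
      ra <- c(a[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(b[j], rb); j <- j - 1L
    }
  }
  blk <- alignment_block(c(A = paste(ra, collapse = ""),
                           B = paste(rb, collapse = "")))
  attr(blk, "score") <- H[n + 1L, m + 1L]
  blk
}

#' Remove alignment columns with gaps or missing data
#'
#' Complete deletion: every column containing `-` or `?` in any row is
#' dropped before distance calculation.
#'
#' @param block An [alignment_block()].
#' @return The block restricted to clean columns; `kept_columns` records
#'   the surviving original column indices.
#' @export
complete_deletion <- function(block) {
  keep <- colSums(block$mat == "-" | block$mat == "?") == 0L
  if (!any(keep)) stop("no columns survive complete deletion", call. = FALSE)
  block$kept_columns <- block$kept_columns[keep]
  block$mat <- block$mat[, keep, drop = FALSE]
  block
}

#' Uncorrected p-distance with bootstrap standard error
#'
#' The p-distance is the proportion of differing sites between two rows of
#' a gap-free alignment. The standard error is the standard deviation of
#' the p-distance over site-bootstrap replicates (columns resampled with
#' replacement), reproducible for a fixed seed.
#'
#' @param block Gap-free [alignment_block()] (apply [complete_deletion()]
#'   first).
#' @param rowA,rowB Row labels or indices (defaults: first two rows).
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `p_dist_estimate`: `p`, `se`, `n_sites`,
#'   `replicates`, `seed`.
#' @export
p_distance <- function(block, rowA = 1L, rowB = 2L, replicates = 1000L,
                       seed = 1L) {
  if (any(block$mat == "-" | block$mat == "?"))
    stop("block contains gaps/missing data; run complete_deletion() first",
         call. = FALSE)
  x <- block$mat[rowA, ]; y <- block$mat[rowB, ]
  n <- length(x)
  if (n == 0L) stop("zero sites", call. = FALSE)
  diff <- x != y
  p <- mean(diff)
  reps <- .with_seed(seed, {
    idx <- matrix(sample.int(n, n * replicates, replace = TRUE),
                  nrow = n, ncol = replicates)
    colMeans(matrix(diff[idx], nrow = n))
  })
  structure(list(p = p, se = stats::sd(reps), n_sites = n,
                 replicates = as.integer(replicates), seed = seed),
            class = "p_dist_estimate")
}

#' @export
print.p_dist_estimate <- function(x, ...) {
  cat(sprintf("p-distance %.4f +/- %.4f (SE, %d bootstrap reps, %d sites)\n",
              x$p, x$se, x$replicates, x$n_sites))
  invisible(x)
}

#' Concatenate per-gene alignment blocks
#'
#' Column-wise concatenation in the given (documented, fixed) gene order;
#' all blocks must carry the same label set.
#'
#' @param per_gene_blocks Non-empty list of [alignment_block()]s.
#' @return One concatenated [alignment_block()].
#' @export
concat_genes <- function(per_gene_blocks) {
  if (length(per_gene_blocks) == 0L) stop("no blocks to concatenate",
                                          call. = FALSE)
  labels <- sort(per_gene_blocks[[1]]$labels)
  mats <- lapply(per_gene_blocks, function(b) {
    if (!identical(sort(b$labels), labels))
      stop("label sets differ between blocks", call. = FALSE)
    b$mat[labels, , drop = FALSE]
  })
  alignment_block(do.call(cbind, mats))
}

#' Sliding-window p-distance along a pairwise alignment
#'
#' Windows are placed in alignment coordinates (width 300, step 10 by
#' default); within each window, columns containing gaps or missing data
#' are dropped and the p-distance is computed over the rest. Windows with
#' zero clean sites yield `NA`.
#'
#' @param block Two-row [alignment_block()] (may contain gaps).
#' @param width,step Window size and step, in alignment columns.
#' @return Data frame: `start`, `center`, `end` (0-based alignment
#'   coordinates), `n_sites`, `p`.
#' @export
sliding_window_distance <- function(block, width = 300L, step = 10L) {
  if (nrow(block$mat) != 2L) stop("need a two-row block", call. = FALSE)
  L <- ncol(block$mat)
  if (width > L) stop("window width exceeds alignment length", call. = FALSE)
  clean <- colSums(block$mat == "-" | block$mat == "?") == 0L
  diff <- clean & (block$mat[1, ] != block$mat[2, ])
  cs_clean <- c(0L, cumsum(clean))
  cs_diff <- c(0L, cumsum(diff))
  starts <- seq.int(0L, L - width, by = step)
  ends <- starts + width
  ns <- cs_clean[ends + 1L] - cs_clean[starts + 1L]
  nd <- cs_diff[ends + 1L] - cs_diff[starts + 1L]
  data.frame(start = starts, center = starts + width / 2, end = ends,
             n_sites = ns, p = ifelse(ns == 0L, NA_real_, nd / ns))
}
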