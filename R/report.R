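# Per-genome and pairwise comparative reports. Reports only aggregate
# module results (plus sums); no report-local statistics.

# non-coding gaps between annotated features, per contig
.ncr_inventory <- function(genome, min_len = 100L) {
  out <- list()
  for (cid in names(genome$contigs)) {
    L <- nchar(genome$contigs[[cid]]$seq)
    f <- genome$features[genome$features$contig_id == cid, ]
    cov <- rep(FALSE, L)
    if (nrow(f)) for (r in seq_len(nrow(f))) {
      if (f$wrap[r]) cov[c(seq_len(f$end[r]), (f$start[r] + 1L):L)] <- TRUE
      else cov[(f$start[r] + 1L):f$end[r]] <- TRUE
    }
    rl <- rle(cov)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths
    keep <- !rl$values & rl$lengths >= min_len
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        contig = cid, start = starts[keep], end = ends[keep],
        length = rl$lengths[keep])
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  do.call(rbind, out)
}

#' Build a per-genome summary report
#'
#' Aggregates contig lengths, base composition, strand weight asymmetry,
#' the per-CDS length/stop table (with amino-acid chain lengths under the
#' incomplete-stop accounting rule), the tRNA census, and an inventory of
#' non-coding regions with their tandem arrays and terminal inverted
#' repeats.
#'
#' @param genome A [mito_genome()].
#' @param ncr_min_len Minimum gap length reported as an NCR (default 100).
#' @param palindrome_window,palindrome_min_len Passed to
#'   [find_terminal_palindromes()] per contig (skipped for short contigs).
#' @return Object of class `genome_report`.
#' @export
build_genome_report <- function(genome, ncr_min_len = 100L,
                                palindrome_window = 500L,
                                palindrome_min_len = 10L) {
  contig_lengths <- vapply(genome$contigs, function(ct) nchar(ct$seq), 0L)
  comp <- base_summary(genome)
  wdiff <- strand_weight_diff(
    paste(vapply(genome$contigs, `[[`, "", "seq"), collapse = ""))
  cds <- genome$features[genome$features$kind == "CDS", ]
  cds_table <- NULL
  if (nrow(cds)) {
    rows <- lapply(seq_len(nrow(cds)), function(r) {
      f <- cds[r, ]
      s <- extract_gene_seq(genome, f)
      status <- classify_stop(s)
      data.frame(gene = f$gene_name, bp = nchar(s),
                 aa = aa_chain_length(nchar(s), status),
                 stop_status = status)
    })
    cds_table <- do.call(rbind, rows)
    cds_table <- cds_table[order(cds_table$gene), ]
    rownames(cds_table) <- NULL
  }
  trna <- genome$features$gene_name[genome$features$kind == "tRNA"]
  ncr <- .ncr_inventory(genome, ncr_min_len)
  arrays <- if (nrow(ncr)) do.call(rbind, lapply(seq_len(nrow(ncr)),
    function(r) {
      ct <- genome$contigs[[ncr$contig[r]]]
      a <- find_tandem_arrays(substr(ct$seq, ncr$start[r] + 1L, ncr$end[r]))
      if (!nrow(a)) return(NULL)
      a$start <- a$start + ncr$start[r]; a$end <- a$end + ncr$start[r]
      cbind(contig = ncr$contig[r], a)
    }))
  pal <- do.call(rbind, lapply(names(genome$contigs), function(cid) {
    ct <- genome$contigs[[cid]]
    if (nchar(ct$seq) < palindrome_window) return(NULL)
    p <- find_terminal_palindromes(ct, window = palindrome_window,
                                   min_len = palindrome_min_len)
    if (!nrow(p)) return(NULL)
    cbind(contig = cid, p)
  }))
  structure(list(
    species = genome$species,
    contig_lengths = contig_lengths,
    total_length = sum(contig_lengths),
    at_percent = comp$at_percent,
    gc_percent = comp$gc_percent,
    heavy_strand = comp$heavy_strand,
    heavy_gt_percent = comp$heavy_gt_percent,
    strand_weight_diff_percent = wdiff,
    cds_table = cds_table,
    trna_census = table(trna),
    trna_duplicated = unique(trna[duplicated(trna)]),
    ncr_inventory = ncr,
    tandem_arrays = arrays,
    terminal_palindromes = pal
  ), class = "genome_report")
}

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf("<genome_report> %s\n", x$species))
  cat(sprintf("  contigs: %s (total %s bp)\n",
              paste(x$contig_lengths, collapse = " + "),
              format(x$total_length, big.mark = ",")))
  cat(sprintf("  AT %.1f%%, GC %.1f%%, heavy-strand (%s) G+T %.1f%%\n",
              x$at_percent, x$gc_percent, x$heavy_strand,
              x$heavy_gt_percent))
  cat(sprintf("  strand weight difference %.3f%%\n",
              x$strand_weight_diff_percent))
  if (!is.null(x$cds_table))
    cat(sprintf("  %d CDS (%d aa total), %d with incomplete stops\n",
                nrow(x$cds_table), sum(x$cds_table$aa),
                sum(x$cds_table$stop_status != "complete")))
  cat(sprintf("  %d tRNA genes; %d NCR(s) >= threshold\n",
              sum(x$trna_census), nrow(x$ncr_inventory)))
  invisible(x)
}

#' Build a pairwise comparison report
#'
#' Aligns each shared CDS as amino acids (complete deletion, p-distance
#' with bootstrap SE), concatenates them, aligns shared rRNA genes as
#' nucleotides with a sliding-window distance profile, tabulates
#' amino-acid-length RSDs, and compares gene orders (breakpoint distance
#' on orders with and without tRNAs, plus an event search on the
#' tRNA-free order). Genes present in only one genome are dropped and
#' listed in `dropped_genes`.
#'
#' @param genomeA,genomeB Annotated [mito_genome()]s.
#' @param seed Seed for the bootstrap.
#' @param replicates Bootstrap replicates (default 1000).
#' @param max_events Bound for the gene-order event search.
#' @param window,step Sliding-window parameters for the rRNA profiles.
#' @return Object of class `comparison_report`.
#' @export
build_comparison_report <- function(genomeA, genomeB, seed = 1L,
                                    replicates = 1000L, max_events = 3L,
                                    window = 300L, step = 10L) {
  fA <- genomeA$features; fB <- genomeB$features
  shared <- intersect(fA$gene_name, fB$gene_name)
  dropped <- setdiff(union(fA$gene_name, fB$gene_name), shared)
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  labA <- genomeA$species; labB <- genomeB$species
  if (labA == labB) labB <- paste0(labB, ".2")

  cds_genes <- sort(intersect(fA$gene_name[fA$kind == "CDS"], shared))
  per_gene <- list(); blocks <- list(); rsd <- list()
  for (g in cds_genes) {
    sA <- extract_gene_seq(genomeA, fA[fA$gene_name == g, ][1, ])
    sB <- extract_gene_seq(genomeB, fB[fB$gene_name == g, ][1, ])
    aaA <- translate_cds(sA, allow_internal_stops = TRUE)
    aaB <- translate_cds(sB, allow_internal_stops = TRUE)
    blk <- global_align(aaA, aaB)
    blk$labels <- c(labA, labB); rownames(blk$mat) <- blk$labels
    blk <- complete_deletion(blk)
    blocks[[g]] <- blk
    per_gene[[g]] <- p_distance(blk, replicates = replicates, seed = seed)
    rsd[[g]] <- data.frame(gene = g, aa_A = nchar(aaA), aa_B = nchar(aaB),
                           rsd_percent = ortholog_rsd(c(nchar(aaA),
                                                        nchar(aaB))))
  }
  concat <- NULL; concat_p <- NULL
  if (length(blocks)) {
    concat <- concat_genes(blocks)
    concat_p <- p_distance(concat, replicates = replicates, seed = seed)
  }

  rrna_genes <- sort(intersect(fA$gene_name[fA$kind == "rRNA"], shared))
  rrna_profiles <- list(); rrna_p <- list()
  for (g in rrna_genes) {
    sA <- extract_gene_seq(genomeA, fA[fA$gene_name == g, ][1, ])
    sB <- extract_gene_seq(genomeB, fB[fB$gene_name == g, ][1, ])
    blk <- global_align(sA, sB)
    blk$labels <- c(labA, labB); rownames(blk$mat) <- blk$labels
    clean <- complete_deletion(blk)
    rrna_p[[g]] <- p_distance(clean, replicates = replicates, seed = seed)
    if (ncol(blk$mat) >= window)
      rrna_profiles[[g]] <- sliding_window_distance(blk, width = window,
                                                    step = step)
  }

  restrict <- function(genome) {
    g2 <- genome
    g2$features <- g2$features[g2$features$gene_name %in% shared, ]
    g2
  }
  ordA <- extract_order(restrict(genomeA))
  ordB <- extract_order(restrict(genomeB))
  ordA_no_t <- extract_order(restrict(genomeA), include_trna = FALSE)
  ordB_no_t <- extract_order(restrict(genomeB), include_trna = FALSE)
  scenario <- infer_events(ordA_no_t, ordB_no_t, max_events = max_events)

  dots <- dotplot_matches(
    paste(vapply(genomeA$contigs, `[[`, "", "seq"), collapse = ""),
    paste(vapply(genomeB$contigs, `[[`, "", "seq"), collapse = ""))

  structure(list(
    pair = c(labA, labB),
    dropped_genes = dropped,
    per_gene_p = per_gene,
    concat_p = concat_p,
    n_concat_sites = if (!is.null(concat)) ncol(concat$mat) else 0L,
    rsd_table = if (length(rsd)) do.call(rbind, rsd) else NULL,
    rrna_p = rrna_p,
    rrna_profiles = rrna_profiles,
    breakpoint_with_trna = breakpoint_distance(ordA, ordB),
    breakpoint_no_trna = breakpoint_distance(ordA_no_t, ordB_no_t),
    event_search = scenario,
    dotplot_n_matches = nrow(dots),
    dotplot_longest = if (nrow(dots)) max(dots$length) else 0L,
    seed = seed
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s\n", x$pair[1], x$pair[2]))
  if (length(x$dropped_genes))
    cat("  dropped (not shared):", paste(x$dropped_genes, collapse = ", "),
        "\n")
  if (!is.null(x$concat_p))
    cat(sprintf("  concatenated aa p-distance %.4f +/- %.4f (%d sites)\n",
                x$concat_p$p, x$concat_p$se, x$concat_p$n_sites))
  for (g in names(x$rrna_p))
    cat(sprintf("  %s nt p-distance %.4f +/- %.4f\n", g, x$rrna_p[[g]]$p,
                x$rrna_p[[g]]$se))
  cat(sprintf("  breakpoint distance %d (with tRNA) / %d (without)\n",
              x$breakpoint_with_trna, x$breakpoint_no_trna))
  if (x$event_search$found)
    cat(sprintf("  gene-order scenario: %d event(s)\n",
                x$event_search$n_events))
  else cat("  gene-order scenario: not found within bound\n")
  cat(sprintf("  dotplot: %d match(es), longest %d bp\n",
              x$dotplot_n_matches, x$dotplot_longest))
  invisible(x)
}
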