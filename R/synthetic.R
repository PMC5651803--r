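# Deterministic synthetic-mitogenome generator with planted truth.
# The generator emulates the structure of long, repeat-rich calanoid
# mitogenomes: 13 CDS + 2 rRNA + 22 tRNA genes, long non-AT-rich NCRs
# carrying TATA tandem arrays, inverted repeats at contig termini,
# incomplete stop codons, planted gene-order events, planted pairwise
# divergence, and uniform error-free read sets at known coverage.

.CDS_ROSTER <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cytb", "nd1",
                 "nd2", "nd3", "nd4", "nd4l", "nd5", "nd6")
.CDS_LENGTHS <- c(714, 162, 1557, 705, 792, 1133, 919, 969, 354, 1302,
                  336, 1711, 474)
.TRNA_ROSTER <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                  "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                  "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                  "trnY")
.RRNA_ROSTER <- c("rrnL", "rrnS")
.RRNA_LENGTHS <- c(1125, 656)
.MINUS_SET <- c("nd1", "nd4", "nd4l", "nd5", "rrnL", "rrnS",
                "trnF", "trnH", "trnP", "trnQ", "trnV")

#' Simulation configuration
#'
#' Defaults mirror the structure of the sequenced calanoid mitogenomes:
#' the 13 protein-coding genes at their published lengths (with the
#' incomplete-stop genes `cytb`, `nd1`, `nd5`), rRNA genes of 1125 and
#' 656 bp, 22 tRNA genes, three long NCRs, overall AT content 58.3%, and
#' 150 bp reads at 50-fold coverage.
#'
#' @param seed Mandatory integer seed.
#' @param n_cds,n_trna,n_rrna Gene counts (taken from fixed rosters).
#' @param ncr_lengths Lengths (bp) of the internal non-coding regions.
#' @param at_content Target genome AT fraction.
#' @param tata_units Copies of the `TATA` unit planted in each NCR.
#' @param palindrome_len Arm length of the terminal inverted repeats.
#' @param divergence_p Default per-site substitution probability for
#'   [diverge_pair()].
#' @param planted_events Rearrangement events (see [apply_events()])
#'   applied to the ancestral order before emission.
#' @param read_coverage,read_len Defaults for [simulate_reads()].
#' @param species Species label of the emitted genome.
#' @param circular Emit a circular contig (default `TRUE`).
#' @param cds_lengths Optional override of the CDS length vector.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, n_cds = 13L, n_trna = 22L, n_rrna = 2L,
                       ncr_lengths = c(3000L, 2500L, 2000L),
                       at_content = 0.583, tata_units = 8L,
                       palindrome_len = 20L, divergence_p = 0,
                       planted_events = list(), read_coverage = 50,
                       read_len = 150L, species = "sim",
                       circular = TRUE, cds_lengths = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(at_content >= 0, at_content <= 1,
            divergence_p >= 0, divergence_p <= 0.75,
            n_cds >= 1L, n_cds <= 13L, n_trna <= 22L, n_rrna <= 2L)
  if (is.null(cds_lengths)) cds_lengths <- .CDS_LENGTHS[seq_len(n_cds)]
  stopifnot(length(cds_lengths) == n_cds, all(cds_lengths >= 9))
  if (any(4L * tata_units > ncr_lengths))
    stop("NCR too short for the planted TATA array", call. = FALSE)
  structure(list(seed = as.integer(seed), n_cds = as.integer(n_cds),
                 n_trna = as.integer(n_trna), n_rrna = as.integer(n_rrna),
                 ncr_lengths = as.integer(ncr_lengths),
                 at_content = at_content, tata_units = as.integer(tata_units),
                 palindrome_len = as.integer(palindrome_len),
                 divergence_p = divergence_p,
                 planted_events = planted_events,
                 read_coverage = read_coverage,
                 read_len = as.integer(read_len),
                 species = species, circular = isTRUE(circular),
                 cds_lengths = as.integer(cds_lengths)),
            class = "sim_config")
}

.random_seq <- function(n, at) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# CDS base-sampling AT adjusted so that stop-codon rejection still hits the
# genome-wide AT target
.cds_at_adjust <- function(at) {
  if (at <= 0 || at >= 1) return(at)
  f <- function(p) {
    pa <- p / 2; pg <- (1 - p) / 2
    ptaa <- pa^3; ptag <- pa^2 * pg
    (3 * p - 3 * ptaa - 2 * ptag) / (3 * (1 - ptaa - ptag)) - at
  }
  stats::uniroot(f, c(max(at - 0.1, 1e-6), min(at + 0.1, 1 - 1e-6)))$root
}

# random in-frame CDS of exactly `bp` nt: ATG start, no internal stop,
# ending per stop status inferred from bp %% 3
.random_cds <- function(bp, at) {
  r <- bp %% 3L
  ncod <- bp %/% 3L
  nbody <- ncod - 1L - (r == 0L)    # codons between ATG and the terminus
  body <- character(0)
  if (nbody > 0L) {
    need <- nbody
    while (need > 0L) {
      cand <- vapply(seq_len(need), function(i) .random_seq(3L, at), "")
      cand <- cand[!cand %in% c("TAA", "TAG")]
      body <- c(body, cand)
      need <- nbody - length(body)
    }
  }
  tail <- c("TAA", "T", "TA")[r + 1L]
  paste0("ATG", paste(body, collapse = ""), tail)
}

#' Simulate an annotated mitogenome with planted truth
#'
#' Deterministic given `config$seed`. Emits a single (by default
#' circular) contig holding the configured gene roster in the ancestral
#' order rearranged by `planted_events`, with small random spacers,
#' internal NCRs carrying planted TATA tandem arrays, and terminal NCRs
#' carrying planted inverted repeats. CDS are valid reading frames under
#' the invertebrate mitochondrial code; genes whose length is not
#' divisible by 3 receive incomplete stops.
#'
#' @param config A [sim_config()].
#' @return List with elements `genome` (a [mito_genome()]) and `truth`
#'   (class `sim_truth`): `ancestral_order`, `events`, `emitted_order`,
#'   `genome_length`, `tata_arrays`, `palindromes`, `realized_at`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    cds <- .CDS_ROSTER[seq_len(config$n_cds)]
    cds_len <- config$cds_lengths
    trna <- .TRNA_ROSTER[seq_len(config$n_trna)]
    rrna <- .RRNA_ROSTER[seq_len(config$n_rrna)]
    rrna_len <- .RRNA_LENGTHS[seq_len(config$n_rrna)]
    # ancestral circular order: anchor cox1 first, tRNAs interleaved,
    # rRNA genes after the last CDS
    genes <- c("cox1", setdiff(cds, "cox1"))
    slots <- length(genes) + 1L
    interleaved <- character(0)
    ti <- 1L
    for (g in seq_along(genes)) {
      interleaved <- c(interleaved, genes[g])
      n_here <- ceiling((length(trna) - ti + 1L) / (length(genes) - g + 1L))
      if (n_here > 0L && ti <= length(trna)) {
        take <- trna[ti:min(ti + n_here - 1L, length(trna))]
        interleaved <- c(interleaved, take)
        ti <- ti + length(take)
      }
    }
    interleaved <- c(interleaved, rrna)
    anc_labels <- ifelse(interleaved %in% .MINUS_SET,
                         paste0("-", interleaved), interleaved)
    ancestral <- signed_gene_order(anc_labels, anchor = "cox1")
    emitted <- apply_events(ancestral, config$planted_events)

    # per-gene sense sequences
    at <- config$at_content
    at_cds <- .cds_at_adjust(at)
    kind_of <- function(g) if (g %in% cds) "CDS"
                           else if (g %in% rrna) "rRNA" else "tRNA"
    gene_seq <- list()
    for (g in interleaved) {
      gene_seq[[g]] <- switch(kind_of(g),
        CDS = .random_cds(cds_len[match(g, cds)], at_cds),
        rRNA = .random_seq(rrna_len[match(g, rrna)], at),
        tRNA = .random_seq(65L, at))
    }

    # NCR insertion slots: spread evenly among the gene gaps (never first)
    n_genes <- length(emitted$labels)
    ncr_after <- if (length(config$ncr_lengths))
      pmin(floor(seq_len(length(config$ncr_lengths)) *
                   n_genes / (length(config$ncr_lengths) + 1L)), n_genes)
    else integer(0)

    plen <- config$palindrome_len
    term_len <- max(120L, 2L * plen + 60L)
    make_terminal <- function(offset) {
      arm <- .random_seq(plen, at)
      pad1 <- .random_seq(10L, at); pad2 <- .random_seq(10L, at)
      rest <- .random_seq(term_len - 2L * plen - 20L, at)
      list(seq = paste0(pad1, arm, pad2, revcomp(arm), rest),
           posA = offset + 10L, posB = offset + 10L + plen + 10L)
    }

    pieces <- character(0)
    pos <- 0L
    feats <- list()
    tata <- list(); pals <- list()
    push <- function(s) { pieces[[length(pieces) + 1L]] <<- s; pos <<- pos + nchar(s) }

    term_head <- make_terminal(0L)
    pals[[1]] <- data.frame(end = "start", posA = term_head$posA,
                            posB = term_head$posB, length = plen)
    push(term_head$seq)
    for (gi in seq_len(n_genes)) {
      lab <- emitted$labels[gi]
      g <- sub("^-", "", lab)
      s <- gene_seq[[g]]
      strand <- if (startsWith(lab, "-")) "-" else "+"
      feats[[length(feats) + 1L]] <- gene_feature(
        gene_name = g, kind = kind_of(g), contig_id = "mt1",
        start = pos, end = pos + nchar(s), strand = strand,
        stop_status = if (kind_of(g) == "CDS") classify_stop(s)
                      else NA_character_)
      push(if (strand == "-") revcomp(s) else s)
      # spacer
      push(.random_seq(sample(4:20, 1L), at))
      hit <- which(ncr_after == gi)
      for (h in hit) {
        len <- config$ncr_lengths[h]
        core <- strrep("TATA", config$tata_units)
        left <- (len - nchar(core)) %/% 2L
        right <- len - nchar(core) - left
        tata[[length(tata) + 1L]] <- data.frame(
          start = pos + left, end = pos + left + nchar(core),
          unit = "AT", copies = nchar(core) / 2)
        push(paste0(.random_seq(left, at), core, .random_seq(right, at)))
      }
    }
    term_tail <- make_terminal(pos)
    pals[[length(pals) + 1L]] <- data.frame(
      end = "end", posA = term_tail$posA, posB = term_tail$posB,
      length = plen)
    push(term_tail$seq)

    seq <- paste(pieces, collapse = "")
    ct <- contig("mt1", seq, circular = config$circular)
    genome <- mito_genome(config$species, list(ct), do.call(rbind, feats))
    bs <- base_summary(genome)
    truth <- structure(list(
      ancestral_order = ancestral,
      events = config$planted_events,
      emitted_order = emitted,
      genome_length = nchar(seq),
      tata_arrays = do.call(rbind, tata),
      palindromes = do.call(rbind, pals),
      realized_at = bs$at_percent / 100
    ), class = "sim_truth")
    list(genome = genome, truth = truth)
  })
}

#' Derive a diverged copy of a genome
#'
#' Substitutes each site independently with probability `p`, choosing
#' uniformly among the three alternative bases (Jukes-Cantor-style); `N`
#' sites are left untouched. Annotations are carried over unchanged. The
#' realized substitution counts (overall and per gene) are recorded in
#' the `divergence_truth` attribute.
#'
#' @param genome A [mito_genome()].
#' @param p Per-site substitution probability in `[0, 0.75]`.
#' @param seed Integer seed.
#' @return The diverged [mito_genome()] with attribute `divergence_truth`
#'   (list: `p`, `n_sites`, `n_substituted`, `per_gene` data frame).
#' @export
diverge_pair <- function(genome, p, seed) {
  stopifnot(p >= 0, p <= 0.75)
  .with_seed(seed, {
    out <- genome
    out$species <- paste0(genome$species, "_div")
    nsub <- 0L; ntot <- 0L
    for (cid in names(out$contigs)) {
      ch <- strsplit(out$contigs[[cid]]$seq, "", fixed = TRUE)[[1]]
      ok <- ch != "N"
      hit <- ok & stats::runif(length(ch)) < p
      if (any(hit)) {
        alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                      nrow = 3,
                      dimnames = list(NULL, c("A", "C", "G", "T")))
        pick <- sample.int(3L, sum(hit), replace = TRUE)
        ch[hit] <- alt[cbind(pick, match(ch[hit], colnames(alt)))]
      }
      nsub <- nsub + sum(hit); ntot <- ntot + sum(ok)
      out$contigs[[cid]]$seq <- paste(ch, collapse = "")
    }
    per_gene <- NULL
    if (nrow(genome$features)) {
      per_gene <- do.call(rbind, lapply(seq_len(nrow(genome$features)),
        function(r) {
          f <- genome$features[r, ]
          s0 <- extract_gene_seq(genome, f)
          s1 <- extract_gene_seq(out, f)
          mm <- sum(strsplit(s0, "")[[1]] != strsplit(s1, "")[[1]])
          data.frame(gene = f$gene_name, n_sites = nchar(s0),
                     n_substituted = mm, p_realized = mm / nchar(s0))
        }))
    }
    attr(out, "divergence_truth") <- list(
      p = p, n_sites = ntot, n_substituted = nsub, per_gene = per_gene)
    out
  })
}

#' Simulate error-free reads at a target coverage
#'
#' Read start positions are uniform over each contig (circular contigs
#' wrap); strands are sampled uniformly. The number of reads per contig is
#' `round(coverage * L / read_len)`.
#'
#' @param genome A [mito_genome()] (or [contig()]).
#' @param coverage Target fold coverage (> 0).
#' @param read_len Read length in bp.
#' @param seed Integer seed.
#' @return Named character vector of read sequences.
#' @export
simulate_reads <- function(genome, coverage, read_len, seed) {
  stopifnot(coverage > 0)
  contigs <- if (inherits(genome, "mito_genome")) genome$contigs
             else list(genome)
  .with_seed(seed, {
    reads <- character(0)
    for (ct in contigs) {
      L <- nchar(ct$seq)
      if (read_len > L) stop("read_len exceeds contig length", call. = FALSE)
      n <- round(coverage * L / read_len)
      src <- if (ct$circular) paste0(ct$seq, substr(ct$seq, 1L, read_len)) else ct$seq
      starts <- if (ct$circular) sample.int(L, n, replace = TRUE)
                else sample.int(L - read_len + 1L, n, replace = TRUE)
      rd <- substring(src, starts, starts + read_len - 1L)
      flip <- stats::runif(n) < 0.5
      rd[flip] <- vapply(rd[flip], revcomp, "", USE.NAMES = FALSE)
      names(rd) <- sprintf("%s_read%06d", ct$id, seq_len(n))
      reads <- c(reads, rd)
    }
    reads
  })
}

#' Write reads as FASTQ
#'
#' @param reads Named character vector (as from [simulate_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+",
                           strrep("I", nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulation truth as JSON
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  x <- list(
    ancestral_order = truth$ancestral_order$labels,
    emitted_order = truth$emitted_order$labels,
    events = truth$events,
    genome_length = truth$genome_length,
    tata_arrays = truth$tata_arrays,
    palindromes = truth$palindromes,
    realized_at = truth$realized_at)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
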