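# Shared fixture builders; all randomness is locally seeded.

rand_dna <- function(n, at = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# a random in-frame CDS with a complete stop, no internal stops
rand_cds <- function(ncod, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  body <- character(0)
  while (length(body) < ncod - 2L) {
    cand <- replicate(ncod, paste(sample(c("A", "C", "G", "T"), 3, TRUE),
                                  collapse = ""))
    body <- c(body, cand[!cand %in% c("TAA", "TAG")])
  }
  paste0("ATG", paste(body[seq_len(ncod - 2L)], collapse = ""), "TAA")
}

# minimal two-gene annotated genome on one circular contig
tiny_genome <- function(seed = 1) {
  set.seed(seed)
  g1 <- rand_cds(40)
  g2 <- rand_cds(30)
  spacer <- rand_dna(50)
  seq <- paste0(g1, spacer, revcomp(g2), rand_dna(60))
  feats <- rbind(
    gene_feature("cox1", "CDS", "c1", 0, nchar(g1), "+",
                 stop_status = "complete"),
    gene_feature("nd2", "CDS", "c1", nchar(g1) + 50,
                 nchar(g1) + 50 + nchar(g2), "-", stop_status = "complete"))
  mito_genome("tiny", list(contig("c1", seq, circular = TRUE)), feats)
}

# random signed order over n genes anchored at cox1
rand_order <- function(n, seed = NULL, p_neg = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sample(paste0("g", 2:n))
  signs <- ifelse(runif(n - 1) < p_neg, "-", "")
  signed_gene_order(c("cox1", paste0(signs, genes)))
}

# random valid event on an n-gene anchored order
rand_event <- function(n, kinds = c("reversal", "transposition",
                                    "reverse_transposition")) {
  kind <- sample(kinds, 1)
  blk <- sort(sample(2:n, 2, replace = TRUE))
  if (kind == "reversal") return(list(kind = kind, block = blk))
  dests <- setdiff(2:(n + 1), blk[1]:(blk[2] + 1))
  if (!length(dests)) return(list(kind = "reversal", block = blk))
  list(kind = kind, block = blk, dest = dests[sample.int(length(dests), 1)])
}
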