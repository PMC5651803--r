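test_that("stop classification covers complete, partial and missing stops", {
  expect_identical(classify_stop("ATGAAATAA"), "complete")
  expect_identical(classify_stop("ATGAAATAG"), "complete")
  expect_identical(classify_stop(paste0(strrep("ATG", 377), "TA")),
                   "partial_TA")  # 1133 bp
  expect_identical(classify_stop("ATGAAAT"), "partial_T")
  expect_identical(classify_stop("ATGAAACAA"), "no_stop")
  expect_identical(classify_stop("ATGAAAG"), "no_stop")
})

test_that("chain-length accounting follows the stop-codon rule", {
  expect_identical(aa_chain_length(714, "complete"), 237L)
  expect_identical(aa_chain_length(1133, "partial_TA"), 377L)
  expect_identical(aa_chain_length(712, "partial_T"), 237L)
  expect_error(aa_chain_length(713, "complete"), "divisible")
  for (k in c(1L, 5L, 100L))
    expect_identical(aa_chain_length(3L * (k + 1L), "complete") + 1L, k + 1L)
  expect_identical(stop_status_from_length(c(714, 712, 1133)),
                   c("complete", "partial_T", "partial_TA"))
})

test_that("four-fold degenerate sites match a per-codon enumeration oracle", {
  code <- mito_code()
  oracle <- function(s) {
    n <- nchar(s) - nchar(s) %% 3
    starts <- seq(1, n - 2, by = 3)
    pos <- integer(0)
    for (st in starts) {
      pre <- substr(s, st, st + 1)
      aas <- code[paste0(pre, c("A", "C", "G", "T"))]
      if (!any(aas == "*") && length(unique(aas)) == 1) pos <- c(pos, st + 1)
    }
    pos
  }
  expect_identical(fourfold_positions("CTACTG")$positions, c(2L, 5L))
  expect_identical(fourfold_positions("ATGAAA")$positions, integer(0))
  expect_identical(fourfold_positions("AGAAGG")$positions, c(2L, 5L))
  for (seed in 1:5) {
    s <- rand_cds(50, seed = seed)
    got <- fourfold_positions(s)
    expect_identical(got$positions, as.integer(oracle(s)))
    expect_true(all(got$positions %% 3 == 2))
    expect_identical(sum(got$counts), length(got$positions))
  }
})

test_that("neutral-site GC skew respects native gene direction", {
  # CDS whose four-fold third positions are all G
  s <- paste0("ATG", strrep("GGG", 20), "TAA")
  g <- mito_genome("x", list(contig("c1", paste0(s, "AAAA"))),
                   gene_feature("f", "CDS", "c1", 0, nchar(s), "+",
                                "complete"))
  f <- g$features[1, ]
  expect_equal(neutral_site_gc_skew(g, f), 1)

  # minus-strand gene: sense skew is minus the skew of the forward-strand
  # complement bases at the same sites
  set.seed(21)
  cds <- rand_cds(80)
  seq <- paste0(rand_dna(30), revcomp(cds), rand_dna(30))
  gm <- mito_genome("y", list(contig("c1", seq)),
                    gene_feature("f", "CDS", "c1", 30, 30 + nchar(cds), "-",
                                 "complete"))
  v <- neutral_site_gc_skew(gm, gm$features[1, ])
  ns <- fourfold_positions(cds)
  sense_bases <- substring(cds, ns$positions + 1, ns$positions + 1)
  anti <- chartr("ACGT", "TGCA", paste(sense_bases, collapse = ""))
  expect_equal(v, -gc_skew(anti))
})

test_that("RSD uses the sample standard deviation and half-up rounding", {
  expect_equal(ortholog_rsd(c(237, 237, 235, 236)), 0.41)
  expect_equal(ortholog_rsd(c(322, 322, 322, 322)), 0.00)
  expect_equal(ortholog_rsd(c(157, 160, 157, 159)), 0.95)
  expect_equal(ortholog_rsd(c(53, 53, 52, 53)), 0.95)
  set.seed(3)
  x <- rnorm(10, 100, 5)
  expect_equal(ortholog_rsd(3 * x), ortholog_rsd(x))
  expect_error(ortholog_rsd(5), "at least 2")
})

test_that("incomplete-stop censuses match the published accounting", {
  tab <- calanus_cds_table()
  new_pair <- tab[tab$species %in% c("glacialis", "finmarchicus"), ]
  expect_identical(incomplete_stop_census(new_pair), 7L)
  expect_identical(incomplete_stop_census(tab), 11L)
  complete_only <- data.frame(bp = c(300, 312, 903))
  expect_identical(incomplete_stop_census(complete_only), 0L)
})

test_that("published chain lengths are reproduced from nucleotide lengths", {
  tab <- calanus_cds_table()
  tab$aa <- aa_chain_length(tab$bp, stop_status_from_length(tab$bp))
  expect_identical(tab$aa, tab$aa_printed)
  totals <- tapply(tab$aa, tab$species, sum)
  expect_identical(as.integer(totals[["glacialis"]]), 3698L)
  expect_identical(as.integer(totals[["finmarchicus"]]), 3701L)
})
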