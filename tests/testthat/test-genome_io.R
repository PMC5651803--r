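test_that("FASTA round trip preserves ids, sequences and circular flags", {
  cts <- list(contig("c1", "ACGTACGT", circular = TRUE),
              contig("c2", "TTTTNACG"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(cts, f)
  back <- read_fasta(f)
  expect_length(back, 2L)
  expect_identical(vapply(back, `[[`, "", "id"), c("c1", "c2"))
  expect_identical(vapply(back, `[[`, "", "seq"),
                   vapply(cts, `[[`, "", "seq"))
  expect_identical(vapply(back, `[[`, TRUE, "circular"), c(TRUE, FALSE))
})

test_that("FASTA reading uppercases and converts U to T", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c1", "acgu", ">c2", "ACGT"), f)
  back <- read_fasta(f)
  expect_identical(back[[1]]$seq, "ACGT")
  expect_identical(back[[2]]$seq, "ACGT")
})

test_that("FASTA errors are informative", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
  expect_error(read_fasta(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("GFF3 coordinates convert 1-based inclusive to 0-based half-open", {
  g <- mito_genome("x", list(contig("c1", "ACGTACGTAC", circular = TRUE)))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t1\t3\t.\t+\t.\tgene=a;stop_status=complete",
               "c1\tsrc\ttRNA\t4\t6\t.\t-\t.\tName=b"), f)
  ft <- read_features(f, g)
  expect_identical(ft$start, c(0L, 3L))
  expect_identical(ft$end, c(3L, 6L))
  expect_identical(ft$strand, c("+", "-"))
  expect_identical(ft$gene_name, c("a", "b"))
})

test_that("feature round trip (incl. origin-spanning wrap dialect) is identity", {
  g <- mito_genome("x", list(contig("c1", "ACGTACGTAC", circular = TRUE)))
  ft <- rbind(
    gene_feature("a", "CDS", "c1", 2, 8, "+", stop_status = "partial_T"),
    gene_feature("b", "tRNA", "c1", 1, 4, "-"),
    gene_feature("w", "CDS", "c1", 8, 3, "+", stop_status = "complete",
                 wrap = TRUE))
  f <- withr::local_tempfile(fileext = ".gff3")
  write_features(ft, f)
  back <- read_features(f, g)
  expect_identical(back, ft)
})

test_that("GFF3 rejects unknown seqids and reversed intervals", {
  g <- mito_genome("x", list(contig("c1", "ACGTACGTAC")))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines("cX\tsrc\tCDS\t1\t3\t.\t+\t.\tgene=a", f)
  expect_error(read_features(f, g), "unknown seqid")
  writeLines("c1\tsrc\tCDS\t5\t3\t.\t+\t.\tgene=a", f)
  expect_error(read_features(f, g), "end < start")
})

test_that("extract_gene_seq honours strand and circular wrap", {
  g <- mito_genome("x", list(contig("c1", "ACGT", circular = TRUE)))
  plus <- gene_feature("p", "CDS", "c1", 0, 3, "+", "complete")
  minus <- gene_feature("m", "CDS", "c1", 0, 3, "-", "complete")
  wrapf <- gene_feature("w", "CDS", "c1", 2, 2, "+", "complete", wrap = TRUE)
  expect_identical(extract_gene_seq(g, plus), "ACG")
  expect_identical(extract_gene_seq(g, minus), "CGT")
  expect_identical(extract_gene_seq(g, wrapf), "GTAC")
  lin <- mito_genome("y", list(contig("c1", "ACGT")))
  expect_error(
    extract_gene_seq(lin, gene_feature("z", "CDS", "c1", 2, 2, "+",
                                       "complete", wrap = TRUE)),
    "linear")
})

test_that("extracted length equals end - start (mod L), strand-independent", {
  set.seed(42)
  L <- 200
  g <- mito_genome("x", list(contig("c1", rand_dna(L), circular = TRUE)))
  for (i in 1:25) {
    s <- sample.int(L, 1) - 1L
    e <- sample.int(L, 1)
    wrap <- s >= e
    for (strand in c("+", "-")) {
      f <- gene_feature("f", "rRNA", "c1", s, e, strand, wrap = wrap)
      want <- if (wrap) L - s + e else e - s
      expect_identical(nchar(extract_gene_seq(g, f)), as.integer(want))
    }
  }
})

test_that("translation follows the invertebrate mitochondrial code", {
  expect_identical(translate_cds("ATGTAA"), "M")
  expect_identical(translate_cds("AGATAA"), "S")   # AGA = Ser in table 5
  expect_identical(translate_cds("ATGTGAAAATAA"), "MWK")  # TGA = Trp
  expect_error(translate_cds("ATGTAAAAATAA"), "internal stop.*2")
  expect_identical(translate_cds("ATGANATAA"), "MX")
  expect_identical(translate_cds("ATGAAAT"), "MK")  # trailing nt ignored
})

test_that("translation agrees with the reference translator on clean CDS", {
  for (seed in 1:5) {
    s <- rand_cds(60, seed = seed)
    ours <- translate_cds(s)
    ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), genetic.code = Biostrings::getGeneticCode("5")))
    ref <- sub("\\*$", "", ref)
    expect_identical(ours, ref)
    # length bookkeeping for a complete-stop CDS
    expect_identical(nchar(ours), (nchar(s) - 3L) %/% 3L)
  }
})
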