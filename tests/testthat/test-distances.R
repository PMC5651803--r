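test_that("global alignment is optimal, symmetric and deterministic", {
  s <- rand_dna(30, seed = 2)
  self <- global_align(s, s)
  expect_equal(attr(self, "score"), nchar(s))
  expect_false(any(self$mat == "-"))

  blk <- global_align("ACGT", "ACT", 1, -1, -2)
  expect_equal(attr(blk, "score"), 1)
  expect_equal(sum(blk$mat == "-"), 1)

  # score agrees with the reference dynamic-programming implementation
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  set.seed(4)
  for (i in 1:8) {
    a <- rand_dna(sample(5:60, 1))
    b <- rand_dna(sample(5:60, 1))
    ours <- attr(global_align(a, b, 1, -1, -2), "score")
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
      type = "global", scoreOnly = TRUE)
    expect_equal(ours, ref)
    expect_equal(attr(global_align(b, a, 1, -1, -2), "score"), ours)
  }
})

test_that("complete deletion drops exactly the gapped/missing columns", {
  blk <- alignment_block(c(a = "ACGTA", b = "AC-TA"))
  out <- complete_deletion(blk)
  expect_identical(out$kept_columns, c(1L, 2L, 4L, 5L))
  gapless <- alignment_block(c(a = "ACGT", b = "ACGT"))
  expect_identical(complete_deletion(gapless)$mat, gapless$mat)
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "G", "T", "-", "?"), 60, TRUE,
                       prob = c(rep(0.22, 4), 0.06, 0.06)),
                nrow = 3)
    blk <- alignment_block(m)
    keep_oracle <- which(apply(m, 2, function(col)
      !any(col %in% c("-", "?"))))
    if (!length(keep_oracle)) {
      expect_error(complete_deletion(blk), "no columns")
    } else {
      expect_identical(complete_deletion(blk)$kept_columns, keep_oracle)
    }
  }
  expect_error(complete_deletion(alignment_block(c(a = "-", b = "A"))),
               "no columns")
})

test_that("p-distance counts mismatches and bootstraps reproducibly", {
  ident <- alignment_block(c(a = "ACGTACGT", b = "ACGTACGT"))
  pd <- p_distance(ident, seed = 1)
  expect_equal(pd$p, 0)
  expect_equal(pd$se, 0)

  pd <- p_distance(alignment_block(c(a = "AAAA", b = "AAAT")), seed = 1)
  expect_equal(pd$p, 0.25)

  gappy <- alignment_block(c(a = "AC-T", b = "ACGT"))
  expect_error(p_distance(gappy), "complete_deletion")

  # symmetry and bit-for-bit reproducibility
  blk <- alignment_block(c(a = rand_dna(500, seed = 5),
                           b = rand_dna(500, seed = 6)))
  p1 <- p_distance(blk, "a", "b", seed = 42)
  p2 <- p_distance(blk, "b", "a", seed = 42)
  expect_identical(p1$p, p2$p)
  expect_identical(p1$se, p2$se)
  expect_identical(p_distance(blk, seed = 42)$se,
                   p_distance(blk, seed = 42)$se)
})

test_that("bootstrap SE approximates the binomial closed form", {
  # 200 mismatches over 1000 sites: p = 0.2
  a <- strrep("A", 1000)
  b <- paste0(strrep("C", 200), strrep("A", 800))
  pd <- p_distance(alignment_block(c(a = a, b = b)), seed = 7,
                   replicates = 1000)
  expect_equal(pd$p, 0.2)
  analytic <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(pd$se - analytic) / analytic, 0.15)
})

test_that("concatenation is additive and order-exchangeable", {
  b1 <- alignment_block(c(a = rand_dna(80, seed = 1),
                          b = rand_dna(80, seed = 2)))
  b2 <- alignment_block(c(b = rand_dna(40, seed = 3),
                          a = rand_dna(40, seed = 4)))
  cc <- concat_genes(list(b1, b2))
  expect_equal(ncol(cc$mat), 120)
  dbl <- concat_genes(list(b1, b1))
  expect_equal(ncol(dbl$mat), 160)
  expect_equal(p_distance(dbl, seed = 1)$p, p_distance(b1, seed = 1)$p)
  expect_equal(p_distance(concat_genes(list(b1, b2)), seed = 1)$p,
               p_distance(concat_genes(list(b2, b1)), seed = 1)$p)
  expect_error(concat_genes(list()), "no blocks")
  b3 <- alignment_block(c(a = "ACGT", z = "ACGT"))
  expect_error(concat_genes(list(b1, b3)), "label sets")
})

test_that("sliding-window distances localize divergence and average to the global p", {
  ident <- alignment_block(c(a = rand_dna(600, seed = 9)))
  ident$mat <- rbind(ident$mat, ident$mat)
  rownames(ident$mat) <- ident$labels <- c("a", "b")
  prof <- sliding_window_distance(ident, width = 100, step = 10)
  expect_true(all(prof$p == 0))

  # planted divergent segment in a conserved background
  set.seed(10)
  a <- rand_dna(2000)
  bch <- strsplit(a, "")[[1]]
  seg <- 701:1300
  flip <- seg[runif(600) < 0.3]
  bch[flip] <- vapply(bch[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  blk <- alignment_block(c(a = a, b = paste(bch, collapse = "")))
  prof <- sliding_window_distance(blk, width = 300, step = 10)
  peak <- prof$center[which.max(prof$p)]
  expect_lt(abs(peak - 1000), 150)

  # partition identity when step == width
  prof2 <- sliding_window_distance(blk, width = 200, step = 200)
  expect_equal(mean(prof2$p), p_distance(blk, seed = 1)$p)
  expect_error(sliding_window_distance(blk, width = 3000), "width")
})
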