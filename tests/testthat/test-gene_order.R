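test_that("normalization anchors, is idempotent and rotation/reflection invariant", {
  o <- signed_gene_order(c("g3", "-cox1", "g2"), normalize = FALSE)
  n1 <- normalize_order(o)
  expect_identical(n1$labels[1], "cox1")
  expect_identical(normalize_order(n1)$labels, n1$labels)
  set.seed(12)
  for (i in 1:10) {
    base <- rand_order(8)$labels
    rot <- sample.int(8, 1)
    rotated <- c(base[rot:8], base[seq_len(rot - 1)])
    expect_identical(signed_gene_order(rotated)$labels, base)
    reflected <- rev(ifelse(startsWith(base, "-"), sub("^-", "", base),
                            paste0("-", base)))
    expect_identical(signed_gene_order(reflected)$labels, base)
  }
  expect_error(signed_gene_order(c("a", "b")), "anchor")
})

test_that("order extraction follows coordinates, strands and the tRNA flag", {
  sim <- simulate_genome(sim_config(seed = 33))
  ord <- extract_order(sim$genome)
  expect_identical(ord$labels, sim$truth$emitted_order$labels)
  no_t <- extract_order(sim$genome, include_trna = FALSE)
  expect_identical(sort(sub("^-", "", no_t$labels)),
                   sort(sub("^-", "", grep("^-?trn",
                                           ord$labels, invert = TRUE,
                                           value = TRUE))))
  g <- tiny_genome()
  expect_identical(extract_order(g)$labels, c("cox1", "-nd2"))
})

test_that("breakpoint distance matches an independent adjacency-set oracle", {
  bp_oracle <- function(a, b) {
    adj <- function(l) {
      w <- c(l, l[1])
      lapply(seq_along(l), function(t) c(w[t], w[t + 1]))
    }
    flip <- function(p) {
      neg <- function(x) ifelse(startsWith(x, "-"), sub("^-", "", x),
                                paste0("-", x))
      c(neg(p[2]), neg(p[1]))
    }
    bset <- adj(b$labels)
    sum(!vapply(adj(a$labels), function(p)
      any(vapply(bset, function(q)
        identical(p, q) || identical(flip(p), q), TRUE)), TRUE))
  }
  o <- rand_order(9, seed = 14)
  expect_identical(breakpoint_distance(o, o), 0L)
  # single reversal of an internal block breaks exactly 2 adjacencies
  for (blk in list(c(2, 2), c(3, 5), c(2, 8), c(4, 9))) {
    o2 <- apply_events(o, list(list(kind = "reversal", block = blk)))
    expect_identical(breakpoint_distance(o, o2), 2L)
  }
  set.seed(15)
  for (i in 1:10) {
    a <- rand_order(7)
    b <- rand_order(7)
    expect_identical(breakpoint_distance(a, b), bp_oracle(a, b))
    expect_identical(breakpoint_distance(a, b), breakpoint_distance(b, a))
  }
})

test_that("event application matches hand-worked permutations and inverts cleanly", {
  o <- signed_gene_order(c("cox1", "g2", "g3", "g4", "g5"))
  expect_identical(apply_events(o, list())$labels, o$labels)
  # reversal of the block (g3, g4)
  rev1 <- apply_events(o, list(list(kind = "reversal", block = c(3, 4))))
  expect_identical(rev1$labels, c("cox1", "g2", "-g4", "-g3", "g5"))
  set.seed(16)
  for (i in 1:20) {
    o <- rand_order(8)
    evs <- lapply(seq_len(sample(1:3, 1)), function(j) rand_event(8))
    there <- apply_events(o, evs)
    back <- apply_events(there, invert_events(evs))
    expect_identical(back$labels, o$labels)
  }
  expect_error(apply_events(o, list(list(kind = "reversal", block = c(1, 2)))),
               "out of range")
})

test_that("the search recovers planted events and agrees with the exact oracle", {
  o <- rand_order(10, seed = 17)
  expect_identical(bfs_min_events(o, o), 0L)
  expect_identical(infer_events(o, o)$n_events, 0L)

  one_rev <- apply_events(o, list(list(kind = "reversal", block = c(4, 7))))
  expect_identical(bfs_min_events(o, one_rev), 1L)
  inf <- infer_events(o, one_rev)
  expect_true(inf$found)
  expect_identical(inf$n_events, 1L)

  # planted single transposition is recovered as one transposition
  tp <- apply_events(o, list(list(kind = "transposition", block = c(3, 5),
                                  dest = 9)))
  inf <- infer_events(o, tp)
  expect_identical(inf$n_events, 1L)
  expect_identical(inf$events[[1]]$kind, "transposition")

  # not-found outcome is explicit
  set.seed(18)
  far <- rand_order(10)
  hard <- infer_events(o, far, max_events = 1)
  if (!hard$found) expect_identical(hard$n_events, NA_integer_)

  # exhaustive small agreement suite (larger suite in the acceptance tests)
  set.seed(19)
  for (i in 1:25) {
    a <- rand_order(8)
    evs <- lapply(seq_len(sample(0:2, 1)), function(j) rand_event(8))
    b <- apply_events(a, evs)
    d <- bfs_min_events(a, b, cap = 2)
    inf <- infer_events(a, b, max_events = 2)
    expect_true(inf$found)
    expect_identical(inf$n_events, d)
    expect_lte(ceiling(breakpoint_distance(a, b) / 3), d)
  }
})

test_that("planted 3-event instances are solved within the event budget", {
  o <- rand_order(15, seed = 20)
  evs <- list(list(kind = "reverse_transposition", block = c(3, 5), dest = 9),
              list(kind = "reverse_transposition", block = c(10, 12),
                   dest = 2),
              list(kind = "reverse_transposition", block = c(6, 7),
                   dest = 14))
  b <- apply_events(o, evs)
  inf <- infer_events(o, b, max_events = 3)
  expect_true(inf$found)
  expect_lte(inf$n_events, 3L)
  expect_gte(inf$n_events, ceiling(breakpoint_distance(o, b) / 3))
  expect_identical(apply_events(o, inf$events)$labels, b$labels)
})

test_that("the 4-taxon scenario recovers star-like truth and respects bounds", {
  anc <- rand_order(7, seed = 22)
  ident <- list(A = anc, B = anc, C = anc, D = anc)
  ps0 <- parsimony_scenario(ident, list(c("A", "B"), c("C", "D")))
  expect_true(ps0$found)
  expect_identical(ps0$total, 0L)

  leaf <- function(ev) apply_events(anc, list(ev))
  orders <- list(
    A = leaf(list(kind = "reversal", block = c(2, 3))),
    B = leaf(list(kind = "reversal", block = c(4, 5))),
    C = leaf(list(kind = "transposition", block = c(2, 2), dest = 6)),
    D = leaf(list(kind = "reversal", block = c(5, 6))))
  ps <- parsimony_scenario(orders, list(c("A", "B"), c("C", "D")), k = 1,
                           cap = 3)
  expect_true(ps$found)
  expect_identical(ps$total, 4L)
  # the total can never beat the hardest leaf pair
  pairmax <- max(apply(utils::combn(names(orders), 2), 2, function(pr)
    bfs_min_events(orders[[pr[1]]], orders[[pr[2]]], cap = 4)))
  expect_gte(ps$total, pairmax)
})
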