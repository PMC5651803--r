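# Signed circular gene orders, breakpoint distance, and rearrangement-event
# search over the three classic event classes (transposition, reversal,
# reverse transposition). Orders are normalized to a fixed anchor gene
# (default cox1, forward); events act on the normalized linearization and
# never move the anchor, so an origin-spanning block is represented by its
# complement.

#' Construct a signed circular gene order
#'
#' @param labels Character vector of signed gene names; a leading `-`
#'   marks a reverse-strand gene (e.g. `c("cox1","-nd2","trnK")`).
#' @param anchor Gene used for rotation/orientation normalization.
#' @param normalize Normalize on construction (default `TRUE`).
#' @return Object of class `signed_gene_order`.
#' @export
signed_gene_order <- function(labels, anchor = "cox1", normalize = TRUE) {
  genes <- sub("^-", "", labels)
  if (anyDuplicated(genes))
    stop("gene labels must be unique up to sign", call. = FALSE)
  x <- structure(list(labels = labels, anchor = anchor),
                 class = "signed_gene_order")
  if (normalize) normalize_order(x) else x
}

#' @export
print.signed_gene_order <- function(x, ...) {
  cat("<signed_gene_order> (anchor ", x$anchor, ")\n  ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Normalize a signed circular order
#'
#' Rotates (and if needed reflects) the circle so the anchor gene comes
#' first with forward sign. Idempotent; rotations and whole-circle
#' reflections of the input normalize identically.
#'
#' @param x A [signed_gene_order()].
#' @return Normalized order.
#' @export
normalize_order <- function(x) {
  lab <- x$labels
  genes <- sub("^-", "", lab)
  i <- match(x$anchor, genes)
  if (is.na(i)) stop("anchor gene '", x$anchor, "' absent", call. = FALSE)
  if (startsWith(lab[i], "-")) {       # reflect: reverse order, flip signs
    lab <- rev(ifelse(startsWith(lab, "-"), sub("^-", "", lab),
                      paste0("-", lab)))
    i <- length(lab) + 1L - i
  }
  if (i > 1L) lab <- c(lab[i:length(lab)], lab[seq_len(i - 1L)])
  x$labels <- lab
  x
}

# -- integer encoding and primitive moves --------------------------------------

.order_ints <- function(x, gene_levels) {
  genes <- sub("^-", "", x$labels)
  idx <- match(genes, gene_levels)
  if (anyNA(idx)) stop("gene label sets differ", call. = FALSE)
  ifelse(startsWith(x$labels, "-"), -idx, idx)
}

.ints_to_order <- function(v, gene_levels, anchor) {
  g <- gene_levels[abs(v)]
  structure(list(labels = ifelse(v < 0, paste0("-", g), g), anchor = anchor),
            class = "signed_gene_order")
}

# move table for an n-gene anchored order: blocks within positions 2..n
.move_cache <- new.env(parent = emptyenv())
.moves <- function(n) {
  key <- as.character(n)
  if (!is.null(.move_cache[[key]])) return(.move_cache[[key]])
  rows <- list()
  for (i in 2:n) for (j in i:n) {
    rows[[length(rows) + 1L]] <- c(1L, i, j, NA_integer_)   # reversal
    for (dest in 2:(n + 1L)) {
      if (dest >= i && dest <= j + 1L) next
      rows[[length(rows) + 1L]] <- c(2L, i, j, dest)        # transposition
      rows[[length(rows) + 1L]] <- c(3L, i, j, dest)        # rev transposition
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("kind", "i", "j", "dest")
  .move_cache[[key]] <- m
  m
}

.apply_move <- function(v, kind, i, j, dest) {
  if (kind == 1L) {
    v[i:j] <- -rev(v[i:j])
    return(v)
  }
  blk <- v[i:j]
  if (kind == 3L) blk <- -rev(blk)
  rest <- v[-(i:j)]
  ins <- if (dest < i) dest else dest - (j - i + 1L)
  append(rest, blk, after = ins - 1L)
}

.KINDS <- c("reversal", "transposition", "reverse_transposition")

# adjacency hash of a signed circular order (both reading directions)
.adj_env <- function(v) {
  e <- new.env(parent = emptyenv(), size = 2L * length(v))
  w <- c(v, v[1L])
  for (t in seq_along(v)) {
    e[[paste(w[t], w[t + 1L])]] <- TRUE
    e[[paste(-w[t + 1L], -w[t])]] <- TRUE
  }
  e
}

.bp_to <- function(v, adj) {
  w <- c(v, v[1L])
  miss <- 0L
  for (t in seq_along(v))
    if (is.null(adj[[paste(w[t], w[t + 1L])]])) miss <- miss + 1L
  miss
}

.state_key <- function(v) paste(v, collapse = ",")

# shared normalization of a pair of orders onto one integer alphabet
.pair_ints <- function(orderA, orderB) {
  gA <- sub("^-", "", orderA$labels)
  gB <- sub("^-", "", orderB$labels)
  if (!setequal(gA, gB)) stop("gene label sets differ", call. = FALSE)
  if (!identical(orderA$anchor, orderB$anchor))
    stop("orders use different anchors", call. = FALSE)
  lev <- c(orderA$anchor, sort(setdiff(gA, orderA$anchor)))
  list(a = .order_ints(normalize_order(orderA), lev),
       b = .order_ints(normalize_order(orderB), lev),
       levels = lev)
}

# -- public operations ---------------------------------------------------------

#' Extract the signed gene order of an annotated genome
#'
#' Genes are listed in forward-coordinate order per contig; multi-contig
#' genomes are concatenated in declared contig order (fragment boundaries
#' recorded in attribute `fragments`). Signs come from the strand. The
#' order is normalized so the anchor gene is first and forward. Duplicate
#' gene names are disambiguated with a `.2` suffix (with a warning).
#'
#' @param genome A [mito_genome()].
#' @param include_trna Keep tRNA genes (default `TRUE`).
#' @param anchor Anchor gene (default `"cox1"`).
#' @return A [signed_gene_order()].
#' @export
extract_order <- function(genome, include_trna = TRUE, anchor = "cox1") {
  f <- genome$features
  if (!include_trna) f <- f[f$kind != "tRNA", ]
  if (!nrow(f)) stop("no features", call. = FALSE)
  parts <- character(0); frag <- integer(0)
  for (cid in names(genome$contigs)) {
    fc <- f[f$contig_id == cid, ]
    if (!nrow(fc)) next
    fc <- fc[order(fc$start), ]
    parts <- c(parts, ifelse(fc$strand == "-",
                             paste0("-", fc$gene_name), fc$gene_name))
    frag <- c(frag, length(parts))
  }
  genes <- sub("^-", "", parts)
  if (anyDuplicated(genes)) {
    warning("duplicate gene labels disambiguated with suffixes")
    dup <- stats::ave(genes, genes, FUN = seq_along)
    genes2 <- ifelse(dup == "1", genes, paste0(genes, ".", dup))
    parts <- ifelse(startsWith(parts, "-"), paste0("-", genes2), genes2)
  }
  out <- signed_gene_order(parts, anchor = anchor)
  attr(out, "fragments") <- frag
  out
}

#' Breakpoint distance between signed circular orders
#'
#' Counts the signed circular adjacencies of `orderA` that are absent from
#' `orderB` (an adjacency `(x, y)` is present if `orderB` contains
#' `(x, y)` or `(-y, -x)`). Symmetric; zero iff the orders are equal.
#'
#' @param orderA,orderB [signed_gene_order()]s over the same gene set.
#' @return Non-negative integer count.
#' @export
breakpoint_distance <- function(orderA, orderB) {
  pr <- .pair_ints(orderA, orderB)
  .bp_to(pr$a, .adj_env(pr$b))
}

#' Apply rearrangement events to a gene order
#'
#' Each event is a list with `kind` (`"reversal"`, `"transposition"` or
#' `"reverse_transposition"`), `block = c(i, j)` and, for transpositions,
#' `dest`. Positions are 1-based indices into the *current* normalized
#' order at each step; blocks must lie in `2..n` (the anchor never moves)
#' and `dest` must fall outside the block.
#'
#' @param order A [signed_gene_order()].
#' @param events List of events (empty list = identity).
#' @return The rearranged, normalized [signed_gene_order()].
#' @export
apply_events <- function(order, events) {
  order <- normalize_order(order)
  lev <- c(order$anchor, sort(setdiff(sub("^-", "", order$labels),
                                      order$anchor)))
  v <- .order_ints(order, lev)
  n <- length(v)
  for (ev in events) {
    kind <- match(ev$kind, .KINDS)
    if (is.na(kind)) stop("unknown event kind: ", ev$kind, call. = FALSE)
    i <- ev$block[1]; j <- ev$block[2]
    if (i < 2L || j < i || j > n)
      stop("block indices out of range", call. = FALSE)
    dest <- if (kind == 1L) NA_integer_ else ev$dest
    if (kind != 1L) {
      if (is.null(dest) || dest < 2L || dest > n + 1L ||
          (dest >= i && dest <= j + 1L))
        stop("destination out of range or inside block", call. = FALSE)
    }
    v <- .apply_move(v, kind, i, j, dest)
  }
  .ints_to_order(v, lev, order$anchor)
}

#' Invert a rearrangement event list
#'
#' Returns the event list that undoes `events` when applied after them.
#'
#' @param events Event list as for [apply_events()].
#' @return Inverted event list.
#' @export
invert_events <- function(events) {
  inv <- lapply(events, function(ev) {
    if (ev$kind == "reversal") return(ev)
    i <- ev$block[1]; j <- ev$block[2]; l <- j - i + 1L
    if (ev$dest < i)
      list(kind = ev$kind, block = c(ev$dest, ev$dest + l - 1L),
           dest = j + 1L)
    else
      list(kind = ev$kind, block = c(ev$dest - l, ev$dest - 1L), dest = i)
  })
  rev(inv)
}

#' Exact minimum rearrangement event count (search oracle)
#'
#' Exact minimal number of events separating two signed circular orders,
#' found by bidirectional breadth-first search over the event graph.
#' Intended as a small-instance oracle: the gene set must be small
#' (<= 12 genes) and the cap low (<= 5).
#'
#' @param orderA,orderB [signed_gene_order()]s over the same gene set.
#' @param cap Search depth bound.
#' @param max_states Guard on the number of stored states.
#' @return Minimal event count, or `-1` if it exceeds `cap`.
#' @export
bfs_min_events <- function(orderA, orderB, cap = 4L, max_states = 2e5) {
  pr <- .pair_ints(orderA, orderB)
  n <- length(pr$a)
  if (n > 12L) stop("oracle limited to <= 12 genes; use infer_events()",
                    call. = FALSE)
  if (cap > 5L) stop("oracle cap limited to <= 5", call. = FALSE)
  if (identical(pr$a, pr$b)) return(0L)
  mv <- .moves(n)
  side <- list(
    list(set = new.env(parent = emptyenv()), level = list(pr$a), d = 0L),
    list(set = new.env(parent = emptyenv()), level = list(pr$b), d = 0L))
  side[[1]]$set[[.state_key(pr$a)]] <- 0L
  side[[2]]$set[[.state_key(pr$b)]] <- 0L
  best <- Inf
  nstored <- 2L
  repeat {
    # expand the side with the smaller frontier while depth budget remains
    can <- vapply(1:2, function(s)
      side[[s]]$d + 1L + side[[3L - s]]$d <= min(cap, best - 1), TRUE)
    if (!any(can)) break
    s <- if (all(can)) which.min(c(length(side[[1]]$level),
                                   length(side[[2]]$level))) else which(can)
    me <- side[[s]]; other <- side[[3L - s]]
    newlevel <- list()
    for (v in me$level) {
      for (r in seq_len(nrow(mv))) {
        child <- .apply_move(v, mv[r, 1L], mv[r, 2L], mv[r, 3L], mv[r, 4L])
        k <- .state_key(child)
        if (!is.null(me$set[[k]])) next
        me$set[[k]] <- me$d + 1L
        nstored <- nstored + 1L
        if (nstored > max_states)
          stop("state space too large; lower cap or gene count",
               call. = FALSE)
        od <- other$set[[k]]
        if (!is.null(od)) best <- min(best, me$d + 1L + od)
        newlevel[[length(newlevel) + 1L]] <- child
      }
    }
    me$level <- newlevel
    me$d <- me$d + 1L
    side[[s]] <- me
  }
  if (is.finite(best)) as.integer(best) else -1L
}

#' Infer a shortest rearrangement-event sequence
#'
#' Iterative-deepening search over transpositions, reversals and reverse
#' transpositions, pruned by the breakpoint lower bound (one event changes
#' at most 3 adjacencies) and ordered by the resulting breakpoint
#' distance. The returned event list replays `orderA` into `orderB`
#' exactly (asserted). A heuristic with an exactness certificate only
#' where [bfs_min_events()] confirms it.
#'
#' @param orderA,orderB [signed_gene_order()]s over the same gene set.
#' @param max_events Depth bound (small; <= 7 typical).
#' @return Object of class `event_search`: `found`, `events` (list as for
#'   [apply_events()]), `n_events`.
#' @export
infer_events <- function(orderA, orderB, max_events = 4L) {
  pr <- .pair_ints(orderA, orderB)
  n <- length(pr$a)
  adjB <- .adj_env(pr$b)
  target <- pr$b
  mv <- .moves(n)
  nmv <- nrow(mv)

  dfs <- function(v, remaining) {
    if (identical(v, target)) return(list())
    if (remaining == 0L) return(NULL)
    children <- vector("list", nmv)
    bps <- integer(nmv)
    for (r in seq_len(nmv)) {
      ch <- .apply_move(v, mv[r, 1L], mv[r, 2L], mv[r, 3L], mv[r, 4L])
      children[[r]] <- ch
      bps[r] <- .bp_to(ch, adjB)
    }
    ord <- order(bps, mv[, 1L], mv[, 2L], mv[, 3L], mv[, 4L])
    for (r in ord) {
      if (ceiling(bps[r] / 3) > remaining - 1L) next
      sub <- dfs(children[[r]], remaining - 1L)
      if (!is.null(sub)) {
        ev <- list(kind = .KINDS[mv[r, 1L]],
                   block = c(mv[r, 2L], mv[r, 3L]))
        if (mv[r, 1L] != 1L) ev$dest <- mv[r, 4L]
        return(c(list(ev), sub))
      }
    }
    NULL
  }

  lb <- ceiling(.bp_to(pr$a, adjB) / 3)
  res <- NULL
  for (depth in lb:max_events) {
    if (depth < 0L) next
    res <- dfs(pr$a, depth)
    if (!is.null(res)) break
  }
  if (is.null(res))
    return(structure(list(found = FALSE, events = list(),
                          n_events = NA_integer_), class = "event_search"))
  # hard postcondition: replaying the events must reproduce orderB
  replay <- apply_events(.ints_to_order(pr$a, pr$levels, orderA$anchor), res)
  stopifnot(identical(.order_ints(replay, pr$levels), target))
  structure(list(found = TRUE, events = res, n_events = length(res)),
            class = "event_search")
}

#' @export
print.event_search <- function(x, ...) {
  if (!x$found) {
    cat("<event_search> no solution within bound\n")
    return(invisible(x))
  }
  cat(sprintf("<event_search> %d event(s)\n", x$n_events))
  for (ev in x$events)
    cat(sprintf("  %s block [%d,%d]%s\n", ev$kind, ev$block[1], ev$block[2],
                if (!is.null(ev$dest)) sprintf(" -> before %d", ev$dest)
                else ""))
  invisible(x)
}

# BFS ball: states within radius k of an order, with exact depths
.ball <- function(v, k, mv, max_states = 2e5) {
  set <- new.env(parent = emptyenv())
  set[[.state_key(v)]] <- 0L
  states <- list(v)
  level <- list(v)
  d <- 0L
  while (d < k) {
    newlevel <- list()
    for (s in level) for (r in seq_len(nrow(mv))) {
      child <- .apply_move(s, mv[r, 1L], mv[r, 2L], mv[r, 3L], mv[r, 4L])
      key <- .state_key(child)
      if (is.null(set[[key]])) {
        set[[key]] <- d + 1L
        states[[length(states) + 1L]] <- child
        newlevel[[length(newlevel) + 1L]] <- child
        if (length(states) > max_states)
          stop("ball too large; lower radius", call. = FALSE)
      }
    }
    level <- newlevel
    d <- d + 1L
  }
  list(states = states, depth = set)
}

#' Most parsimonious 4-taxon rearrangement scenario
#'
#' For four leaf orders on an unrooted tree `((L1,L2),(L3,L4))`, proposes
#' the two internal-node orders from the intersection of radius-`k` event
#' balls around each cherry's leaves, minimizing the total event count
#' over the five edges (leaf edges plus the internal edge); exact event
#' counts come from [bfs_min_events()].
#'
#' @param orders Named list of four [signed_gene_order()]s.
#' @param tree List of two character vectors naming the cherries, e.g.
#'   `list(c("A","B"), c("C","D"))`.
#' @param k Ball radius around each leaf (default 1).
#' @param cap Depth cap for internal-edge distances.
#' @return Object of class `parsimony_scenario`: `found`, `internal`
#'   (two orders), `total`, `edge_events` (per-edge event lists).
#' @export
parsimony_scenario <- function(orders, tree, k = 1L, cap = 4L) {
  stopifnot(length(orders) == 4L, length(tree) == 2L)
  leaves <- unlist(tree)
  if (!setequal(leaves, names(orders)))
    stop("tree leaves must match order names", call. = FALSE)
  anchor <- orders[[1]]$anchor
  lev <- c(anchor, sort(setdiff(sub("^-", "", orders[[1]]$labels), anchor)))
  ints <- lapply(orders, function(o) .order_ints(normalize_order(o), lev))
  n <- length(ints[[1]])
  mv <- .moves(n)

  cherry_candidates <- function(pair) {
    b1 <- .ball(ints[[pair[1]]], k, mv)
    b2 <- .ball(ints[[pair[2]]], k, mv)
    keys2 <- b2$depth
    keep <- Filter(function(s) !is.null(keys2[[.state_key(s)]]), b1$states)
    list(states = keep, d1 = b1$depth, d2 = keys2)
  }
  c1 <- cherry_candidates(tree[[1]])
  c2 <- cherry_candidates(tree[[2]])
  if (!length(c1$states) || !length(c2$states))
    return(structure(list(found = FALSE, internal = NULL, total = NA_integer_,
                          edge_events = NULL), class = "parsimony_scenario"))
  best <- NULL; best_total <- Inf; best_keys <- c("", "")
  for (s1 in c1$states) for (s2 in c2$states) {
    k1 <- .state_key(s1); k2 <- .state_key(s2)
    o1 <- .ints_to_order(s1, lev, anchor)
    o2 <- .ints_to_order(s2, lev, anchor)
    dint <- bfs_min_events(o1, o2, cap = cap)
    if (dint < 0L) next
    total <- c1$d1[[k1]] + c1$d2[[k1]] + dint + c2$d1[[k2]] + c2$d2[[k2]]
    if (total < best_total ||
        (total == best_total && paste(k1, k2) < paste(best_keys[1],
                                                      best_keys[2]))) {
      best_total <- total
      best <- list(o1, o2)
      best_keys <- c(k1, k2)
    }
  }
  if (is.null(best))
    return(structure(list(found = FALSE, internal = NULL, total = NA_integer_,
                          edge_events = NULL), class = "parsimony_scenario"))
  edges <- list(
    c(tree[[1]][1], "internal1"), c(tree[[1]][2], "internal1"),
    c("internal1", "internal2"),
    c(tree[[2]][1], "internal2"), c(tree[[2]][2], "internal2"))
  node_order <- c(orders, list(internal1 = best[[1]], internal2 = best[[2]]))
  edge_events <- lapply(edges, function(e)
    infer_events(node_order[[e[1]]], node_order[[e[2]]],
                 max_events = max(k, cap))$events)
  names(edge_events) <- vapply(edges, paste, "", collapse = "--")
  structure(list(found = TRUE, internal = best,
                 total = as.integer(best_total), edge_events = edge_events),
            class = "parsimony_scenario")
}

#' @export
print.parsimony_scenario <- function(x, ...) {
  if (!x$found) cat("<parsimony_scenario> no scenario within bound\n")
  else cat(sprintf("<parsimony_scenario> total %d event(s) over 5 edges\n",
                   x$total))
  invisible(x)
}

#' Read/write plain-text gene-order files
#'
#' One genome per line: `species: gene1, -gene2, ...`.
#'
#' @param orders Named list of [signed_gene_order()]s.
#' @param path File path.
#' @return `path` invisibly ([write_orders()]); named list ([read_orders()]).
#' @export
write_orders <- function(orders, path) {
  writeLines(vapply(names(orders), function(nm)
    paste0(nm, ": ", paste(orders[[nm]]$labels, collapse = ", ")), ""),
    path)
  invisible(path)
}

#' @rdname write_orders
#' @param anchor Anchor passed to [signed_gene_order()].
#' @export
read_orders <- function(path, anchor = "cox1") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    labs <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    signed_gene_order(labs, anchor = anchor)
  })
  names(out) <- vapply(lines, function(ln)
    trimws(strsplit(ln, ":", fixed = TRUE)[[1]][1]), "")
  out
}
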