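#' @keywords internal
"_PACKAGE"

# -- internal sequence helpers -------------------------------------------------

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @return The reverse-complemented string; `N` maps to `N`.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# vectorised base counting; N never counted
.base_counts <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"),
    N = sum(ch == "N"))
}

# -- domain constructors -------------------------------------------------------

#' Create a contig
#'
#' A contig is one assembled sequence with a circularity flag. Sequences are
#' stored uppercase over `{A,C,G,T,N}`; `U` is converted to `T` on input.
#'
#' @param id Unique contig identifier.
#' @param seq DNA string.
#' @param circular Logical; `TRUE` for a closed circle.
#' @return An object of class `contig`.
#' @export
contig <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- chartr("u", "t", toupper(seq))
  seq <- chartr("U", "T", seq)
  .check_dna(seq, paste0("contig '", id, "'"))
  structure(list(id = id, seq = seq, circular = isTRUE(circular)),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig> %s: %d bp%s\n", x$id, nchar(x$seq),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Create a gene feature
#'
#' Coordinates are 0-based half-open on the forward strand of the contig.
#' Features that span the origin of a circular contig have `start >= end`;
#' the feature then runs from `start` to the contig end and wraps to `end`.
#'
#' @param gene_name Gene label (e.g. `"cox1"`, `"rrnL"`, `"trnK"`).
#' @param kind One of `"CDS"`, `"rRNA"`, `"tRNA"`.
#' @param contig_id Contig the feature lives on.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param stop_status For CDS: `"complete"`, `"partial_TA"`, `"partial_T"`,
#'   `"no_stop"` or `NA` (infer later). Non-CDS features get
#'   `"not_applicable"`.
#' @param wrap Logical: feature spans the origin of a circular contig.
#' @return One-row data frame (the feature-table row format).
#' @export
gene_feature <- function(gene_name, kind, contig_id, start, end, strand,
                         stop_status = NA_character_, wrap = FALSE) {
  kind <- match.arg(kind, c("CDS", "rRNA", "tRNA"))
  strand <- match.arg(strand, c("+", "-"))
  start <- as.integer(start); end <- as.integer(end)
  if (!wrap && (start < 0L || end <= start))
    stop("need 0 <= start < end for non-wrapping feature ", gene_name,
         call. = FALSE)
  if (kind != "CDS") stop_status <- "not_applicable"
  data.frame(gene_name = gene_name, kind = kind, contig_id = contig_id,
             start = start, end = end, strand = strand,
             stop_status = stop_status, wrap = isTRUE(wrap),
             stringsAsFactors = FALSE)
}

#' Assemble a mitochondrial genome object
#'
#' @param species Species label.
#' @param contigs List of [contig()] objects (ids must be unique).
#' @param features Feature table: rows as produced by [gene_feature()].
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(species, contigs, features = NULL) {
  if (inherits(contigs, "contig")) contigs <- list(contigs)
  ids <- vapply(contigs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate contig ids", call. = FALSE)
  names(contigs) <- ids
  if (is.null(features))
    features <- gene_feature("x", "CDS", "x", 0, 3, "+")[0, ]
  if (nrow(features)) {
    miss <- setdiff(unique(features$contig_id), ids)
    if (length(miss))
      stop("features reference unknown contig(s): ",
           paste(miss, collapse = ","), call. = FALSE)
    for (r in seq_len(nrow(features))) {
      f <- features[r, ]
      L <- nchar(contigs[[f$contig_id]]$seq)
      if (f$wrap && !contigs[[f$contig_id]]$circular)
        stop("wrap feature ", f$gene_name, " on linear contig", call. = FALSE)
      if (f$end > L || f$start >= L)
        stop("feature ", f$gene_name, " out of range on ", f$contig_id,
             call. = FALSE)
    }
    cds <- features[features$kind == "CDS", ]
    key <- paste(cds$contig_id, cds$start, cds$end, cds$strand)
    if (anyDuplicated(key)) stop("duplicate CDS coordinates", call. = FALSE)
  }
  structure(list(species = species, contigs = contigs, features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  L <- sum(vapply(x$contigs, function(ct) nchar(ct$seq), 0L))
  cat(sprintf("<mito_genome> %s: %d contig(s), %d bp, %d feature(s)\n",
              x$species, length(x$contigs), L, nrow(x$features)))
  if (nrow(x$features))
    print(table(x$features$kind))
  invisible(x)
}

# -- FASTA ---------------------------------------------------------------------

#' Read a FASTA file into a list of contigs
#'
#' Sequences are uppercased and `U` is converted to `T`. A contig is flagged
#' circular when its header carries a whitespace-separated `circular` token
#' (the dialect written by [write_fasta()]).
#'
#' @param path FASTA file.
#' @return List of [contig()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  lapply(seq_along(set), function(i) {
    toks <- strsplit(headers[i], "[ \t]+")[[1]]
    contig(id = toks[1], seq = as.character(set[[i]]),
           circular = "circular" %in% toks[-1])
  })
}

#' Write contigs to FASTA
#'
#' @param contigs List of [contig()] objects or a [mito_genome()].
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 60L) {
  if (inherits(contigs, "mito_genome")) contigs <- contigs$contigs
  if (inherits(contigs, "contig")) contigs <- list(contigs)
  seqs <- Biostrings::BStringSet(vapply(contigs, `[[`, "", "seq"))
  names(seqs) <- vapply(contigs, function(ct)
    if (ct$circular) paste(ct$id, "circular") else ct$id, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# -- GFF3 (subset, with a documented circular-wrap dialect) --------------------

# Origin-spanning features on circular contigs are encoded with start > end
# (1-based) plus attribute circular_wrap=true; plain GFF3 cannot express them.

#' Read a GFF3 feature table
#'
#' Reads the GFF3 subset written by [write_features()]: 1-based inclusive
#' coordinates converted to 0-based half-open; gene names taken from the
#' `gene` (or `Name`) attribute; optional `stop_status` and
#' `circular_wrap` attributes.
#'
#' @param path GFF3 file.
#' @param genome A [mito_genome()] whose contig ids the seqids must match.
#' @return Feature table (data frame).
#' @export
read_features <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop("malformed GFF3 line ", i, ": expected 9 fields", call. = FALSE)
    if (!f[1] %in% names(genome$contigs))
      stop("unknown seqid '", f[1], "' at line ", i, call. = FALSE)
    attrs <- strsplit(strsplit(f[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    av <- vapply(attrs, function(x) if (length(x) == 2) x[2] else "", "")
    names(av) <- vapply(attrs, `[[`, "", 1L)
    gname <- if (!is.na(av["gene"]) && nzchar(av["gene"])) av[["gene"]]
             else if ("Name" %in% names(av)) av[["Name"]]
             else stop("no gene/Name attribute at line ", i, call. = FALSE)
    s1 <- as.integer(f[4]); e1 <- as.integer(f[5])
    wrap <- identical(unname(av["circular_wrap"]), "true")
    if (!wrap && e1 < s1)
      stop("end < start at line ", i,
           " (use circular_wrap=true for origin-spanning features)",
           call. = FALSE)
    out[[i]] <- gene_feature(
      gene_name = gname, kind = f[3], contig_id = f[1],
      start = s1 - 1L, end = e1, strand = f[7],
      stop_status = if ("stop_status" %in% names(av)) av[["stop_status"]]
                    else NA_character_,
      wrap = wrap)
  }
  do.call(rbind, out)
}

#' Write a feature table as GFF3
#'
#' @param features Feature table (rows from [gene_feature()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (r in seq_len(nrow(features))) {
    f <- features[r, ]
    attrs <- paste0("gene=", f$gene_name)
    if (!is.na(f$stop_status) && f$stop_status != "not_applicable")
      attrs <- paste0(attrs, ";stop_status=", f$stop_status)
    if (f$wrap) attrs <- paste0(attrs, ";circular_wrap=true")
    writeLines(paste(f$contig_id, "mitocomp", f$kind, f$start + 1L, f$end,
                     ".", f$strand, ".", attrs, sep = "\t"), con)
  }
  invisible(path)
}

# -- extraction & translation --------------------------------------------------

#' Extract the sense-strand sequence of a feature
#'
#' Returns the forward-strand slice for `+` features and its reverse
#' complement for `-` features. Origin-spanning features on circular contigs
#' concatenate the contig tail and head.
#'
#' @param genome A [mito_genome()].
#' @param feature One row of the genome's feature table.
#' @return DNA string read in the feature's transcription direction.
#' @export
extract_gene_seq <- function(genome, feature) {
  ct <- genome$contigs[[feature$contig_id]]
  if (is.null(ct)) stop("unknown contig ", feature$contig_id, call. = FALSE)
  L <- nchar(ct$seq)
  if (feature$wrap) {
    if (!ct$circular) stop("wrap feature on linear contig", call. = FALSE)
    s <- paste0(substr(ct$seq, feature$start + 1L, L),
                substr(ct$seq, 1L, feature$end))
  } else {
    if (feature$end > L) stop("feature out of range", call. = FALSE)
    s <- substr(ct$seq, feature$start + 1L, feature$end)
  }
  if (feature$strand == "-") revcomp(s) else s
}

#' The invertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map for NCBI translation table 5 (the invertebrate
#' mitochondrial code: `AGA`/`AGG` = Ser, `TGA` = Trp, stops `TAA`/`TAG`),
#' taken from the Biostrings genetic-code tables.
#'
#' @param table_id Translation-table id (default `"5"`).
#' @return Named character vector of 64 codons; stops are `"*"`.
#' @export
mito_code <- function(table_id = "5") {
  Biostrings::getGeneticCode(as.character(table_id))
}

#' Translate a coding sequence
#'
#' Codons are read in frame 0. A trailing incomplete codon (1-2 nt) is
#' ignored; a terminal stop codon is excluded from the chain; an internal
#' stop is an error unless `allow_internal_stops` is set (useful for
#' diverged or draft sequences), in which case it is kept as `*`. Codons
#' containing `N` (or any ambiguity) translate to `X`.
#'
#' @param cds_seq In-frame coding sequence (length >= 3).
#' @param code Codon map, as from [mito_code()].
#' @param allow_internal_stops Keep internal stops as `*` instead of
#'   raising an error.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds_seq, code = mito_code(),
                          allow_internal_stops = FALSE) {
  n <- nchar(cds_seq)
  if (n < 3L) stop("CDS shorter than one codon", call. = FALSE)
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(cds_seq, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  ncod <- length(aa)
  stops <- which(aa == "*")
  if (length(stops)) {
    internal <- stops[stops < ncod]
    if (length(internal) && !allow_internal_stops)
      stop("internal stop codon at codon index ", internal[1], call. = FALSE)
    if (aa[ncod] == "*") aa <- aa[-ncod]
  }
  paste(aa, collapse = "")
}
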