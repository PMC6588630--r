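# Readers and writers for the external formats the pipeline touches:
# FASTA sequences and alignments, Newick trees, 12-column tabular homology
# hits, GFF-lite annotations, and delimited count matrices. Coordinates are
# 1-based inclusive throughout (the R/Bioconductor convention); minus-strand
# features are stored on forward coordinates with an explicit strand flag.

#' Read a FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a named character vector
#' of upper-case residue strings. Names are the first whitespace-delimited
#' token of each header; full headers are kept in the `"description"`
#' attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA input: ", path)
  desc <- names(ss)
  ids <- sub("\\s.*$", "", desc)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- toupper(as.character(ss))
  names(out) <- ids
  attr(out, "description") <- desc
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Requires unique leaf
#' labels and rejects malformed input.
#'
#' @param path Path to a Newick file (first tree is returned).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt)
}

#' Parse a Newick string into a tree
#'
#' @param text Newick string.
#' @return An [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) stop("Newick parse error: unbalanced parentheses")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("Newick parse error")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch lengths in tree")
  }
  tr
}

#' Write a tree to Newick
#'
#' @param tree An [ape::phylo] object.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

.hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

# Canonical hit table: forward subject coordinates plus a strand flag.
# Idempotent: already-normalized rows (strand column present, coordinates
# sorted) pass through unchanged.
normalize_hits <- function(df) {
  if (is.null(df$strand)) {
    df$strand <- ifelse(df$sstart > df$send, "-", "+")
  }
  s1 <- pmin(df$sstart, df$send)
  s2 <- pmax(df$sstart, df$send)
  df$sstart <- s1
  df$send <- s2
  df
}

#' Read a 12-column tabular homology hit file
#'
#' Reads the standard 12-column tabular output of protein-to-genome homology
#' searches (query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, e-value, bit
#' score). Subject coordinates are normalized to the forward strand with a
#' `strand` flag; rows with e-value above `e_cutoff` are dropped.
#'
#' @param path Path to a tab-delimited hit file (no header).
#' @param e_cutoff Maximum e-value retained (default `Inf`, keep all).
#' @return A `data.frame` with the 12 standard columns plus `strand`.
#' @export
read_hits_table <- function(path, e_cutoff = Inf) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("hit table format error: expected 12 tab-delimited columns, got ",
         nf[which(nf != 12L)[1]], " on line ", which(nf != 12L)[1])
  }
  m <- do.call(rbind, fields)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                   pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                   mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                   qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                   sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                   evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  if (any(df$evalue < 0)) stop("negative e-value in hit table")
  df <- normalize_hits(df)
  df[df$evalue <= e_cutoff, , drop = FALSE]
}

empty_hits <- function() {
  df <- data.frame(qseqid = character(0), sseqid = character(0),
                   pident = numeric(0), length = integer(0),
                   mismatch = integer(0), gapopen = integer(0),
                   qstart = integer(0), qend = integer(0),
                   sstart = integer(0), send = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   stringsAsFactors = FALSE)
  df$strand <- character(0)
  df
}

#' Write a hit table in 12-column tabular form
#'
#' Minus-strand rows are written with subject coordinates swapped back to
#' their native (descending) orientation.
#'
#' @param hits Hit `data.frame` as returned by [read_hits_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  out <- hits
  minus <- out$strand == "-"
  tmp <- out$sstart[minus]
  out$sstart[minus] <- out$send[minus]
  out$send[minus] <- tmp
  utils::write.table(out[, .hit_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write GFF-lite annotations
#'
#' GFF-lite is the 9-column annotation table used for mined gene loci:
#' seqid, source, type, start, end, score, strand, frame, attributes
#' (`key=value` pairs separated by `;`). Coordinates are 1-based inclusive.
#'
#' @param path File path.
#' @return A `data.frame` with one row per feature and parsed attributes kept
#'   as the raw `attributes` string.
#' @export
read_gff_lite <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                          col.names = c("seqid", "source", "type", "start",
                                        "end", "score", "strand", "frame",
                                        "attributes"),
                          colClasses = c("character", "character", "character",
                                         "integer", "integer", "character",
                                         "character", "character", "character"),
                          stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("GFF-lite error: start > end")
  df
}

#' @rdname read_gff_lite
#' @param gff GFF-lite `data.frame`.
#' @param header Optional comment lines (without leading `#`).
#' @export
write_gff_lite <- function(gff, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# One GFF attribute string from a named list.
gff_attributes <- function(...) {
  kv <- list(...)
  paste(paste0(names(kv), "=", unlist(kv)), collapse = ";")
}

gff_attr_get <- function(attributes, key) {
  m <- regmatches(attributes,
                  regexpr(paste0("(^|;)", key, "=[^;]*"), attributes))
  out <- rep(NA_character_, length(attributes))
  hit <- lengths(regmatches(attributes,
                            gregexpr(paste0("(^|;)", key, "="), attributes))) > 0
  out[hit] <- sub(paste0("^;?", key, "="), "", m)
  out
}

#' Read or write a delimited matrix with row labels
#'
#' Count/repertoire matrices are tab-delimited with a header row; the first
#' column holds row labels (species or gene ids). Non-numeric columns (for
#' example an `ecotype` column) are returned as attributes.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames; non-numeric columns attached as
#'   attributes by column name.
#' @export
read_matrix_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = 1)
  is_num <- vapply(df, is.numeric, logical(1))
  m <- as.matrix(df[, is_num, drop = FALSE])
  for (nm in names(df)[!is_num]) attr(m, nm) <- stats::setNames(df[[nm]], rownames(df))
  m
}

#' @rdname read_matrix_table
#' @param m Numeric matrix with dimnames; extra per-row columns may be passed
#'   via `extra` (named list of vectors aligned with rows).
#' @param extra Named list of per-row annotation columns.
#' @export
write_matrix_table <- function(m, path, extra = NULL) {
  df <- as.data.frame(m, check.names = FALSE)
  if (!is.null(extra)) for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  utils::write.table(cbind(id = rownames(m), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
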