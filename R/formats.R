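# Readers and writers for the standard formats the pipeline touches.
#
# Coordinate conventions, fixed once at the boundary:
#   * BED / depth intervals: 0-based half-open.
#   * GFF3: 1-based inclusive.
#   * All internal window arithmetic: 0-based half-open.

DNA_LETTERS <- c("A", "C", "G", "T", "N")
AA_MISSING <- c("-", "?", "X")

#' Read a FASTA file of sequences
#'
#' Sequences are uppercased on read. Genome sequences (`alphabet = "dna"`)
#' may contain only A, C, G, T and N, so downstream GC computation is
#' deterministic; ambiguity codes other than N are rejected.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` to enforce the A/C/G/T/N alphabet, `"any"` to
#'   accept arbitrary residues (amino acids, gaps).
#' @return A named character vector of uppercase sequences, in file order.
#'   Names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path, alphabet = c("dna", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stopf("%s: not a FASTA file (must begin with '>')", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stopf("%s: empty sequence identifier", path)
  if (anyDuplicated(ids)) {
    stopf("%s: duplicate sequence id '%s'", path, ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stopf("%s: empty sequence for id '%s'", path, ids[nchar(seqs) == 0L][1])
  }
  if (alphabet == "dna") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stopf("%s: sequence '%s' contains characters outside A/C/G/T/N",
            path, ids[bad][1])
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a 4-column depth BED (bedgraph dialect)
#'
#' Intervals are 0-based half-open and returned sorted by (scaffold, start).
#' Positions absent from the file are depth 0 by convention; sparse emitters
#' omit zero-coverage runs.
#'
#' @param path path to a tab-separated file with columns
#'   scaffold, start, end, depth.
#' @return A data frame with columns `scaffold`, `start`, `end`, `depth`.
#' @export
read_depth_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stopf("%s: no data lines", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1]
    stopf("%s: line %d has %d columns, expected 4", path, lineno[i], nf[i])
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  depth <- suppressWarnings(as.numeric(m[, 4]))
  bad <- is.na(start) | is.na(end) | is.na(depth)
  if (any(bad)) stopf("%s: line %d: non-numeric field", path, lineno[bad][1])
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stopf("%s: line %d: start %s >= end %s", path, lineno[i], m[i, 2], m[i, 3])
  }
  if (any(start < 0)) stopf("%s: negative start position", path)
  if (any(depth < 0)) {
    stopf("%s: line %d: negative depth", path, lineno[which(depth < 0)[1]])
  }
  out <- data.frame(scaffold = m[, 1], start = start, end = end, depth = depth,
                    stringsAsFactors = FALSE)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write depth intervals as a 4-column BED
#'
#' @param intervals data frame with `scaffold`, `start`, `end`, `depth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_depth_bed <- function(intervals, path) {
  stopifnot(all(c("scaffold", "start", "end", "depth") %in% names(intervals)))
  writeLines(sprintf("%s\t%d\t%d\t%g", intervals$scaffold,
                     as.integer(intervals$start), as.integer(intervals$end),
                     intervals$depth), path)
  invisible(path)
}

HIT_COLUMNS <- c("query", "subject", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "qstart", "qend", "sstart",
                 "send", "evalue", "bitscore")

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Exactly the 12 standard columns are required; `#` comment lines are
#' skipped. E-values in scientific notation are parsed as numbers.
#'
#' @param path path to a tab-separated hit table.
#' @return A data frame with the 12 standard columns
#'   (query, subject, pct_identity, aln_length, mismatches, gap_opens,
#'   qstart, qend, sstart, send, evalue, bitscore).
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stopf("hit table not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stopf("%s: no data lines", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stopf("%s: line %d has %d columns, expected 12", path, lineno[i], nf[i])
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  out <- data.frame(
    query = m[, 1], subject = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$evalue) || anyNA(out$bitscore) || anyNA(out$aln_length)) {
    bad <- which(is.na(out$evalue) | is.na(out$bitscore) |
                   is.na(out$aln_length))[1]
    stopf("%s: line %d: non-numeric field", path, lineno[bad])
  }
  if (any(out$evalue < 0)) {
    stopf("%s: line %d: negative e-value", path,
          lineno[which(out$evalue < 0)[1]])
  }
  if (any(out$aln_length <= 0)) {
    stopf("%s: line %d: non-positive alignment length", path,
          lineno[which(out$aln_length <= 0)[1]])
  }
  out
}

#' Read a GFF3 annotation
#'
#' Coordinates stay 1-based inclusive. `ID` and `Parent` attributes are
#' extracted into their own columns; a feature with several parents keeps
#' them comma-separated in `Parent` (split downstream).
#'
#' @param path path to a GFF3 file.
#' @return A data frame with columns `scaffold`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase`, `ID`, `Parent`, `attributes` (the
#'   raw attribute string).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stopf("%s: no feature lines", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1]
    stopf("%s: line %d has %d columns, expected 9", path, lineno[i], nf[i])
  }
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    stopf("%s: line %d: non-numeric coordinate", path,
          lineno[which(is.na(start) | is.na(end))[1]])
  }
  if (any(start > end)) {
    i <- which(start > end)[1]
    stopf("%s: line %d: start %d > end %d", path, lineno[i], start[i], end[i])
  }
  if (any(!m[, 7] %in% c("+", "-", "."))) {
    stopf("%s: line %d: invalid strand", path,
          lineno[which(!m[, 7] %in% c("+", "-", "."))[1]])
  }
  attr_field <- function(attrs, key) {
    vapply(regmatches(attrs, gregexpr(paste0("(^|;)\\s*", key, "=[^;]*"),
                                      attrs)),
           function(x) {
             if (length(x) == 0L) NA_character_
             else sub(paste0("^.*", key, "="), "", x[1])
           }, character(1))
  }
  data.frame(
    scaffold = m[, 1], source = m[, 2], type = m[, 3],
    start = start, end = end,
    score = suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6]))),
    strand = m[, 7], phase = m[, 8],
    ID = attr_field(m[, 9], "ID"),
    Parent = attr_field(m[, 9], "Parent"),
    attributes = m[, 9],
    stringsAsFactors = FALSE
  )
}

#' Read an aligned FASTA file as a per-locus alignment
#'
#' All rows must have equal length; `-`, `?` and `X` are preserved verbatim.
#'
#' @param path path to an aligned FASTA file.
#' @param locus_id alignment identifier; defaults to the file name without
#'   extension.
#' @return A `locus_msa` object: a list with `locus_id` and `seqs`
#'   (named character vector of equal-length, uppercase rows).
#' @export
read_msa_fasta <- function(path, locus_id = NULL) {
  seqs <- read_fasta(path, alphabet = "any")
  if (is.null(locus_id)) {
    locus_id <- tools::file_path_sans_ext(basename(path))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stopf("%s: ragged alignment (row lengths %s)", path,
          paste(sort(unique(lens)), collapse = ", "))
  }
  new_msa(locus_id, seqs)
}

#' Construct a per-locus alignment object
#'
#' @param locus_id alignment identifier.
#' @param seqs named character vector of equal-length aligned sequences.
#' @return A `locus_msa` object.
#' @export
new_msa <- function(locus_id, seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stopf("alignment %s: duplicate taxon '%s'", locus_id,
          names(seqs)[duplicated(names(seqs))][1])
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stopf("alignment %s: rows have unequal lengths", locus_id)
  }
  structure(list(locus_id = locus_id, seqs = toupper(seqs)),
            class = "locus_msa")
}

#' @export
print.locus_msa <- function(x, ...) {
  cat(sprintf("<locus_msa> %s: %d taxa x %d sites\n", x$locus_id,
              length(x$seqs), nchar(x$seqs[[1]])))
  invisible(x)
}

#' Write a per-locus alignment to aligned FASTA
#'
#' @param msa a `locus_msa` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "locus_msa"))
  write_fasta(msa$seqs, path)
}

#' Read a Newick tree
#'
#' @param path_or_text a file path, or a Newick string ending in `;`.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path_or_text) {
  txt <- if (file.exists(path_or_text)) {
    paste(readLines(path_or_text), collapse = "")
  } else {
    path_or_text
  }
  txt <- trimws(txt)
  if (!endsWith(txt, ";")) stopf("Newick string lacks terminal ';'")
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tr)) stopf("malformed Newick string")
  if (anyDuplicated(tr$tip.label)) stopf("duplicate leaf labels in tree")
  tr
}

#' Write a tree as Newick
#'
#' Branch lengths are written with 10 significant digits so a
#' parse-write cycle round-trips topology, labels and lengths.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path, or `NULL` to return the string.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Convert SAM alignments to depth intervals
#'
#' Thin ingestion contract for alignment input: primary alignments with
#' mapping quality at or above `min_mapq` contribute 1 to per-base depth
#' over their reference span (CIGAR M/D/N/=/X consume reference). The
#' result is merged into 0-based half-open constant-depth intervals; all
#' downstream logic consumes those.
#'
#' @param path path to a SAM file.
#' @param scaffold_lengths named vector of scaffold lengths; defaults to
#'   the `@SQ` header lines.
#' @param min_mapq minimum mapping quality (default 0).
#' @return A data frame of depth intervals (`scaffold`, `start`, `end`,
#'   `depth`), zero-depth runs omitted.
#' @export
sam_to_depth <- function(path, scaffold_lengths = NULL, min_mapq = 0) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & !grepl("^\\s*$", lines)]
  if (is.null(scaffold_lengths)) {
    sq <- strsplit(hdr[startsWith(hdr, "@SQ")], "\t", fixed = TRUE)
    sn <- vapply(sq, function(x) sub("^SN:", "", x[startsWith(x, "SN:")][1]),
                 character(1))
    ln <- vapply(sq, function(x) {
      as.numeric(sub("^LN:", "", x[startsWith(x, "LN:")][1]))
    }, numeric(1))
    scaffold_lengths <- stats::setNames(ln, sn)
  }
  if (length(scaffold_lengths) == 0L) stopf("%s: no @SQ header lines", path)
  cov <- lapply(scaffold_lengths, function(L) numeric(L))
  for (l in rec) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next           # unmapped
    if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) next  # not primary
    if (as.integer(f[5]) < min_mapq) next
    rname <- f[3]
    if (!rname %in% names(cov)) stopf("%s: alignment to unknown scaffold '%s'",
                                      path, rname)
    pos <- as.integer(f[4])                    # 1-based leftmost
    ops <- regmatches(f[6], gregexpr("[0-9]+[MIDNSHP=X]", f[6]))[[1]]
    at <- pos
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      o <- sub("[0-9]+", "", op)
      if (o %in% c("M", "D", "N", "=", "X")) {
        if (o %in% c("M", "=", "X")) {
          idx <- at:(at + n - 1L)
          cov[[rname]][idx] <- cov[[rname]][idx] + 1
        }
        at <- at + n
      }
    }
  }
  out <- list()
  for (s in names(cov)) {
    v <- cov[[s]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values > 0
    if (any(nz)) {
      out[[s]] <- data.frame(scaffold = s, start = starts[nz], end = ends[nz],
                             depth = r$values[nz], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), depth = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
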