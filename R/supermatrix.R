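# Phylogenomic supermatrix curation: per-locus missingness and occupancy
# filters, neighbor-joining screens for branch-length outliers and
# paralogous loci, and partitioned concatenation.

#' Missing-character set for amino-acid alignments
#'
#' `-`, `?` and `X` (case-insensitive) count as missing.
#' @keywords internal
is_missing_char <- function(chars) {
  toupper(chars) %in% AA_MISSING
}

msa_char_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
  rownames(m) <- names(msa$seqs)
  m
}

#' Remove high-missingness taxa from one alignment
#'
#' A taxon's non-missing count is compared with the per-locus maximum
#' non-missing count; a taxon is removed when its missing fraction
#' (relative to that maximum) strictly exceeds `max_missing`. Columns are
#' left untouched.
#'
#' @param msa a `locus_msa`.
#' @param max_missing removal threshold (default 0.5, strict `>`).
#' @return A list: `msa` (filtered) and `occupancy` (data frame `taxon`,
#'   `nonmissing`, `fraction_missing`, `removed`).
#' @export
filter_taxa <- function(msa, max_missing = 0.5) {
  stopifnot(inherits(msa, "locus_msa"))
  m <- msa_char_matrix(msa)
  nonmissing <- rowSums(!matrix(is_missing_char(m), nrow = nrow(m)))
  lmax <- max(nonmissing)
  if (lmax == 0) stopf("alignment %s: all characters missing", msa$locus_id)
  frac <- (lmax - nonmissing) / lmax
  removed <- frac > max_missing
  if (all(removed)) stopf("alignment %s: all taxa removed", msa$locus_id)
  occ <- data.frame(taxon = names(msa$seqs), nonmissing = as.integer(nonmissing),
                    fraction_missing = frac, removed = removed,
                    stringsAsFactors = FALSE)
  rownames(occ) <- NULL
  list(msa = new_msa(msa$locus_id, msa$seqs[!removed]), occupancy = occ)
}

#' Occupancy filter over a set of loci
#'
#' A locus is kept when it represents strictly more than `min_frac` of the
#' full taxon list and always includes `required_taxon` (the focal species).
#'
#' @param msas list of `locus_msa` objects.
#' @param full_taxa the complete taxon list.
#' @param min_frac minimum represented fraction (default 0.8, strict `>`).
#' @param required_taxon taxon that must be present in every kept locus.
#' @return A list: `kept`, `dropped` (lists of `locus_msa`), and `report`
#'   (data frame `locus_id`, `n_taxa`, `occupancy`, `has_required`, `kept`).
#' @export
locus_occupancy_filter <- function(msas, full_taxa, min_frac = 0.8,
                                   required_taxon) {
  stopifnot(length(full_taxa) >= 1L)
  if (!required_taxon %in% full_taxa) {
    stopf("required taxon '%s' not in the full taxon list", required_taxon)
  }
  rows <- lapply(msas, function(msa) {
    present <- intersect(names(msa$seqs), full_taxa)
    occ <- length(present) / length(full_taxa)
    hasreq <- required_taxon %in% names(msa$seqs)
    data.frame(locus_id = msa$locus_id, n_taxa = length(msa$seqs),
               occupancy = occ, has_required = hasreq,
               kept = occ > min_frac && hasreq, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(kept = msas[report$kept], dropped = msas[!report$kept],
       report = report)
}

#' Pairwise uncorrected p-distances of an alignment
#'
#' Proportion of differing characters over jointly non-missing sites for
#' each taxon pair. Errors when a pair shares fewer than `min_overlap`
#' jointly non-missing sites.
#'
#' @param msa a `locus_msa`.
#' @param min_overlap minimum jointly non-missing sites per pair (default 20).
#' @return A symmetric distance matrix.
#' @export
pdistance_matrix <- function(msa, min_overlap = 20) {
  m <- msa_char_matrix(msa)
  n <- nrow(m)
  ok <- !matrix(is_missing_char(m), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      joint <- ok[i, ] & ok[j, ]
      if (sum(joint) < min_overlap) {
        stopf("alignment %s: taxa '%s' and '%s' share only %d sites (< %d)",
              msa$locus_id, rownames(m)[i], rownames(m)[j], sum(joint),
              min_overlap)
      }
      d[i, j] <- d[j, i] <- mean(m[i, joint] != m[j, joint])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic NJ agglomeration; negative branch lengths are clamped to 0.
#'
#' @param d symmetric distance matrix with at least 3 taxa.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_from_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stopf("NJ needs at least 3 taxa")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining screening tree of one alignment
#'
#' p-distances via [pdistance_matrix()] followed by [nj_from_dist()]. This
#' is a screening heuristic for curation, not phylogenetic inference.
#'
#' @inheritParams pdistance_matrix
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(msa, min_overlap = 20) {
  if (length(msa$seqs) < 3L) {
    stopf("alignment %s: NJ needs at least 3 taxa", msa$locus_id)
  }
  nj_from_dist(pdistance_matrix(msa, min_overlap = min_overlap))
}

terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  term <- tree$edge[, 2] <= ntip
  stats::setNames(tree$edge.length[term], tree$tip.label[tree$edge[term, 2]])
}

#' Flag taxa with outlying terminal branch lengths
#'
#' A leaf is flagged when its terminal branch exceeds `k` times the median
#' terminal branch and also exceeds the absolute `floor` (so short trees do
#' not produce spurious flags). This automates the visual screen for
#' aberrant sequences with explicit, reported thresholds.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param k multiple of the median terminal branch (default 5).
#' @param floor absolute minimum flagged length (default 0.05).
#' @return Character vector of flagged taxon names (possibly empty).
#' @export
flag_branch_outliers <- function(tree, k = 5, floor = 0.05) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  tb <- terminal_branch_lengths(tree)
  med <- stats::median(tb)
  names(tb)[tb > k * med & tb > floor]
}

# Internal splits of an unrooted tree: for each internal edge, the tip set
# on the child side, with the edge's length. Sides are canonicalized to the
# side not containing the first tip label.
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  internal <- which(tree$edge[, 2] > ntip)
  if (length(internal) == 0L) return(list())
  # tips descending from each node, accumulated children-first
  desc <- vector("list", max(tree$edge))
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(internal, function(e) {
    side <- desc[[tree$edge[e, 2]]]
    if (tree$tip.label[1] %in% side) side <- setdiff(tree$tip.label, side)
    list(side = sort(side), length = tree$edge.length[e])
  })
}

group_is_monophyletic <- function(tree, members) {
  tips <- tree$tip.label
  members <- sort(intersect(members, tips))
  if (length(members) < 2L) return(TRUE)
  if (length(members) >= length(tips) - 1L) return(TRUE)  # complement <= 1 leaf
  canon <- if (tips[1] %in% members) sort(setdiff(tips, members)) else members
  for (sp in tree_splits(tree)) {
    if (identical(sp$side, canon)) return(TRUE)
  }
  FALSE
}

#' Flag a locus tree as paralog-contaminated
#'
#' A locus is flagged when some reference clade (from the published
#' phylogeny) is non-monophyletic in the tree AND an internal edge whose
#' length is at least `edge_frac` of the total tree length separates
#' members of that clade — the signature of a deep gene duplication
#' dominating the tree. Reference-group members absent from the locus are
#' ignored; groups with fewer than 2 present members are skipped.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param reference_groups named list of character vectors (expected clades).
#' @param edge_frac fraction of total tree length an internal edge must
#'   reach to count as dominant (default 0.2).
#' @return A list: `flag` (logical), `group` (name of the triggering group
#'   or `NA`), `edge_length`, `total_length`.
#' @export
flag_paralogs <- function(tree, reference_groups, edge_frac = 0.2) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  total <- sum(tree$edge.length)
  splits <- tree_splits(tree)
  tips <- tree$tip.label
  for (gname in names(reference_groups)) {
    members <- intersect(reference_groups[[gname]], tips)
    if (length(members) < 2L) next
    if (group_is_monophyletic(tree, members)) next
    for (sp in splits) {
      if (sp$length < edge_frac * total) next
      inside <- sum(members %in% sp$side)
      if (inside > 0 && inside < length(members)) {
        return(list(flag = TRUE, group = gname, edge_length = sp$length,
                    total_length = total))
      }
    }
  }
  list(flag = FALSE, group = NA_character_, edge_length = NA_real_,
       total_length = total)
}

#' Concatenate loci into a partitioned supermatrix
#'
#' Loci are concatenated in input order; taxa absent from a locus are
#' padded with `-`. Partitions are recorded 1-based inclusive; per-taxon
#' missingness counts `-`, `?` and `X` over the full matrix length.
#'
#' @param msas list of `locus_msa` objects with unique locus ids.
#' @param full_taxa the taxon list defining the matrix rows.
#' @return A `supermatrix` object: list with `taxa`, `seqs` (named character
#'   vector), `partitions` (data frame `locus_id`, `start`, `end`), and
#'   `missing_fraction` (named numeric).
#' @export
concatenate_loci <- function(msas, full_taxa) {
  if (length(msas) == 0L) stopf("no loci to concatenate")
  ids <- vapply(msas, function(m) m$locus_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate locus id '%s'", ids[duplicated(ids)][1])
  stopifnot(length(full_taxa) >= 1L, !anyDuplicated(full_taxa))
  lens <- vapply(msas, function(m) nchar(m$seqs[[1]]), numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  pieces <- lapply(msas, function(m) {
    L <- nchar(m$seqs[[1]])
    extra <- setdiff(names(m$seqs), full_taxa)
    if (length(extra) > 0L) {
      stopf("locus %s: taxon '%s' not in the full taxon list",
            m$locus_id, extra[1])
    }
    out <- stats::setNames(rep(strrep("-", L), length(full_taxa)), full_taxa)
    out[names(m$seqs)] <- m$seqs
    out
  })
  seqs <- stats::setNames(
    vapply(full_taxa, function(t) {
      paste(vapply(pieces, `[[`, character(1), t), collapse = "")
    }, character(1)), full_taxa)
  total <- sum(lens)
  missing_fraction <- vapply(seqs, function(s) {
    sum(is_missing_char(strsplit(s, "", fixed = TRUE)[[1]])) / total
  }, numeric(1))
  structure(list(taxa = full_taxa, seqs = seqs,
                 partitions = data.frame(locus_id = ids, start = starts,
                                         end = ends, stringsAsFactors = FALSE),
                 missing_fraction = missing_fraction),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d sites, %d partitions\n",
              length(x$taxa), nchar(x$seqs[[1]]), nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix as NEXUS with a sets (charset) block
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus_supermatrix <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  nchar_total <- nchar(sm$seqs[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(sm$taxa),
                       nchar_total),
               "  FORMAT DATATYPE=PROTEIN MISSING=? GAP=-;",
               "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", format(sm$taxa), sm$seqs), con)
  writeLines(c("  ;", "END;", "", "BEGIN SETS;"), con)
  writeLines(sprintf("  CHARSET %s = %d-%d;", sm$partitions$locus_id,
                     sm$partitions$start, sm$partitions$end), con)
  writeLines("END;", con)
  invisible(path)
}

#' Read back a supermatrix written by [write_nexus_supermatrix()]
#'
#' @param path NEXUS path.
#' @return A `supermatrix` object reconstructed from the file.
#' @export
read_nexus_supermatrix <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#NEXUS", lines[1])) stopf("%s: not a NEXUS file", path)
  mstart <- grep("^\\s*MATRIX\\s*$", lines)[1]
  mend <- which(grepl("^\\s*;\\s*$", lines) & seq_along(lines) > mstart)[1]
  if (is.na(mstart) || is.na(mend)) stopf("%s: no MATRIX block", path)
  rows <- trimws(lines[(mstart + 1):(mend - 1)])
  rows <- rows[rows != ""]
  taxa <- sub("\\s.*$", "", rows)
  seqs <- stats::setNames(sub("^\\S+\\s+", "", rows), taxa)
  cs <- grep("^\\s*CHARSET\\s", lines, value = TRUE)
  locus_id <- sub("^\\s*CHARSET\\s+(\\S+)\\s*=.*$", "\\1", cs)
  rng <- sub("^.*=\\s*([0-9]+)-([0-9]+);.*$", "\\1 \\2", cs)
  rngm <- do.call(rbind, lapply(strsplit(rng, " "), as.integer))
  total <- nchar(seqs[[1]])
  missing_fraction <- vapply(seqs, function(s) {
    sum(is_missing_char(strsplit(s, "", fixed = TRUE)[[1]])) / total
  }, numeric(1))
  structure(list(taxa = taxa, seqs = seqs,
                 partitions = data.frame(locus_id = locus_id,
                                         start = rngm[, 1], end = rngm[, 2],
                                         stringsAsFactors = FALSE),
                 missing_fraction = missing_fraction),
            class = "supermatrix")
}

#' Write a supermatrix as relaxed PHYLIP
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_supermatrix <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa), nchar(sm$seqs[[1]])), con)
  writeLines(sprintf("%s  %s", sm$taxa, sm$seqs), con)
  invisible(path)
}

#' Write a RAxML-style partition file
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @param datatype partition model prefix (default `"WAG"`, customary for
#'   amino-acid partitions).
#' @return `path`, invisibly.
#' @export
write_raxml_partitions <- function(sm, path, datatype = "WAG") {
  stopifnot(inherits(sm, "supermatrix"))
  writeLines(sprintf("%s, %s = %d-%d", datatype, sm$partitions$locus_id,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}

#' Curate loci and build the supermatrix
#'
#' The full screening chain over a set of per-locus alignments: (1) remove
#' high-missingness taxa within each locus; (2) keep loci with occupancy
#' strictly above `min_frac` that include `required_taxon`; (3) build an NJ
#' screening tree, remove branch-length outlier taxa, and drop loci flagged
#' as paralog-contaminated; (4) re-apply the missingness and occupancy
#' rules; (5) concatenate survivors into a partitioned supermatrix.
#'
#' @param msas list of `locus_msa` objects.
#' @param full_taxa full taxon list.
#' @param required_taxon taxon required in every kept locus.
#' @param reference_groups named list of expected clades for the paralog
#'   screen (`NULL` to skip it).
#' @param max_missing per-taxon missingness threshold (default 0.5).
#' @param min_frac occupancy threshold (default 0.8).
#' @param k,floor branch-outlier thresholds (see [flag_branch_outliers()]).
#' @param edge_frac paralog-screen threshold (see [flag_paralogs()]).
#' @param min_overlap NJ pairwise-overlap requirement.
#' @return A list: `supermatrix`, `kept` (list of curated `locus_msa`),
#'   `report` (per-locus data frame with the decisions and reasons).
#' @export
curate_loci <- function(msas, full_taxa, required_taxon,
                        reference_groups = NULL, max_missing = 0.5,
                        min_frac = 0.8, k = 5, floor = 0.05,
                        edge_frac = 0.2, min_overlap = 20) {
  rows <- list()
  kept <- list()
  occ_ok <- function(msa) {
    length(intersect(names(msa$seqs), full_taxa)) / length(full_taxa) > min_frac &&
      required_taxon %in% names(msa$seqs)
  }
  for (msa in msas) {
    rec <- list(locus_id = msa$locus_id, taxa_removed_missingness = "",
                taxa_removed_outliers = "", paralog_flag = FALSE,
                paralog_group = NA_character_, retained = FALSE, reason = "")
    ft <- filter_taxa(msa, max_missing = max_missing)
    rec$taxa_removed_missingness <-
      paste(ft$occupancy$taxon[ft$occupancy$removed], collapse = ",")
    cur <- ft$msa
    if (!occ_ok(cur)) {
      rec$reason <- "occupancy"
    } else if (length(cur$seqs) < 3L) {
      rec$reason <- "fewer than 3 taxa"
    } else {
      tr <- nj_tree(cur, min_overlap = min_overlap)
      out <- flag_branch_outliers(tr, k = k, floor = floor)
      if (length(out) > 0L) {
        rec$taxa_removed_outliers <- paste(out, collapse = ",")
        cur <- new_msa(cur$locus_id, cur$seqs[!names(cur$seqs) %in% out])
      }
      if (!occ_ok(cur) || length(cur$seqs) < 3L) {
        rec$reason <- "occupancy after outlier removal"
      } else {
        if (length(out) > 0L) tr <- nj_tree(cur, min_overlap = min_overlap)
        if (!is.null(reference_groups)) {
          pf <- flag_paralogs(tr, reference_groups, edge_frac = edge_frac)
          rec$paralog_flag <- pf$flag
          rec$paralog_group <- pf$group
        }
        if (rec$paralog_flag) {
          rec$reason <- "paralog"
        } else {
          # second missingness pass after any taxon removal
          cur <- filter_taxa(cur, max_missing = max_missing)$msa
          if (!occ_ok(cur)) {
            rec$reason <- "occupancy after second missingness filter"
          } else {
            rec$retained <- TRUE
            rec$reason <- "retained"
            kept[[length(kept) + 1L]] <- cur
          }
        }
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  sm <- if (length(kept) > 0L) concatenate_loci(kept, full_taxa) else NULL
  list(supermatrix = sm, kept = kept, report = report)
}
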