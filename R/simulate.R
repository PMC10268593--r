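# Seeded synthetic-data generators. Every generator is a pure function of
# (config, seed): the RNG kind is pinned and the caller's RNG state is
# restored, so identical inputs give identical bytes.
#
# The generators emulate the study conditions of a male phasmid genome:
# autosomal scaffolds at copy ratio 1 and one X scaffold at copy ratio 0.5,
# binned long-read depth with a unimodal GC bias and negative-binomial
# (overdispersed) noise, a marker-hit table in which a tunable fraction of
# conserved X-linked markers hit the X and the rest distribute in
# proportion to autosome length, per-locus amino-acid alignments with taxon
# dropout and injected deep paralogs, and a multi-exon GFF3 annotation.

#' Simulation configuration
#'
#' Defaults are the study conditions of the coverage analysis: a male
#' genome with 11 autosomes of 0.5-3 Mb and one 1 Mb X at copy ratio 0.5,
#' 30x base depth in 10 kb bins, a quadratic-unimodal GC bias
#' g(gc) = max(eps, 1 - beta (gc - gc0)^2) with gc0 = 0.42, beta = 4,
#' eps = 0.1, and negative-binomial dispersion theta = 10
#' (variance mu + mu^2/theta). Marker tables place each of 100 markers on
#' the X with probability 0.6, the remainder length-proportionally.
#' Locus alignments hold 12 taxa by 500 amino-acid sites with 10% taxon
#' dropout; paralog loci regraft a taxon subset on an internal edge of
#' length 5x the tree height. Annotations draw 1 + Geometric(0.25) exons
#' per transcript with log-normal exon/intron lengths; the intron median
#' 1075 with sdlog 0.75 gives a log-normal mean of ~1424, a realistic
#' insect intron scale.
#'
#' @param ... overrides of the defaults listed above.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_autosomes = 11L,
    autosome_length_range = c(5e5, 3e6),
    x_length = 1e6,
    base_depth = 30,
    x_copy_ratio = 0.5,
    gc0 = 0.42, gc_beta = 4, gc_eps = 0.1,
    gc_block_range = c(0.30, 0.55),
    nb_theta = 10,
    bin_size = 10000,
    n_markers = 100L, p_x = 0.6, decoy_max = 3L,
    n_taxa = 12L, n_sites = 500L, n_loci = 200L,
    dropout_q = 0.1, paralog_frac = 0.5, paralog_delta_mult = 5,
    edge_length_range = c(0.01, 0.05),
    n_transcripts = 500L, exon_geom_p = 0.25,
    exon_median = 250, exon_sdlog = 0.6,
    intron_median = 1075, intron_sdlog = 0.75
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) stopf("unknown sim_config field '%s'", unknown[1])
  cfg[names(over)] <- over
  stopifnot(cfg$n_autosomes >= 1, cfg$base_depth > 0, cfg$nb_theta > 0,
            cfg$bin_size >= 1, cfg$p_x >= 0, cfg$p_x <= 1,
            cfg$dropout_q >= 0, cfg$dropout_q < 1,
            cfg$x_copy_ratio > 0, cfg$x_copy_ratio <= 1,
            cfg$x_length >= 2 * cfg$bin_size,
            cfg$autosome_length_range[1] >= 2 * cfg$bin_size)
  class(cfg) <- "sim_config"
  cfg
}

#' GC bias factor
#'
#' `g(gc) = max(eps, 1 - beta (gc - gc0)^2)`: a unimodal depth bias peaking
#' at `gc0`, floored at `eps`.
#'
#' @param gc GC fractions.
#' @param cfg a [sim_config()].
#' @return Bias factors in (0, 1].
#' @export
gc_bias_factor <- function(gc, cfg = sim_config()) {
  pmax(cfg$gc_eps, 1 - cfg$gc_beta * (gc - cfg$gc0)^2)
}

sample_bases <- function(n, gc_target) {
  prob <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
            (1 - gc_target) / 2)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE,
                                             prob = prob)])
}

#' Simulate a male genome with one X scaffold
#'
#' Scaffolds are i.i.d. bases generated blockwise (blocks of `bin_size`),
#' each block's GC target drawn uniformly over `gc_block_range`, so every
#' scaffold spans the genome-wide GC range as real chromosome-scale
#' scaffolds do. One scaffold, of length `x_length`, is designated the X.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list: `seqs` (named character vector), `truth` (list with
#'   `x_scaffold`, `scaffold_lengths`, `copy_ratio`, `block_gc` data frame).
#' @export
simulate_genome <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    n <- cfg$n_autosomes + 1L
    names_all <- sprintf("scaffold_%02d", seq_len(n))
    x_idx <- sample.int(n, 1L)
    lens <- numeric(n)
    lens[-x_idx] <- round(stats::runif(cfg$n_autosomes,
                                       cfg$autosome_length_range[1],
                                       cfg$autosome_length_range[2]))
    lens[x_idx] <- cfg$x_length
    names(lens) <- names_all
    seqs <- character(n)
    block_rows <- vector("list", n)
    for (i in seq_len(n)) {
      starts <- seq(0, lens[i] - 1, by = cfg$bin_size)
      ends <- pmin(starts + cfg$bin_size, lens[i])
      tg <- stats::runif(length(starts), cfg$gc_block_range[1],
                         cfg$gc_block_range[2])
      seqs[i] <- paste(vapply(seq_along(starts), function(b) {
        sample_bases(ends[b] - starts[b], tg[b])
      }, character(1)), collapse = "")
      block_rows[[i]] <- data.frame(scaffold = names_all[i], start = starts,
                                    end = ends, target_gc = tg,
                                    stringsAsFactors = FALSE)
    }
    names(seqs) <- names_all
    cr <- stats::setNames(rep(1, n), names_all)
    cr[x_idx] <- cfg$x_copy_ratio
    list(seqs = seqs,
         truth = list(x_scaffold = names_all[x_idx],
                      scaffold_lengths = lens,
                      copy_ratio = cr,
                      block_gc = do.call(rbind, block_rows)))
  })
}

#' Simulate binned long-read depth over a simulated genome
#'
#' Each bin's mean depth is one negative-binomial draw with mean
#' `mu = base_depth * copy_ratio * g(gc)` and dispersion `nb_theta`
#' (variance `mu + mu^2/theta`), where `gc` is the realized GC of the bin
#' window. Depth is emitted as per-bin-constant intervals (a bedgraph-style
#' per-base BED when written).
#'
#' @param genome output of [simulate_genome()].
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list: `intervals` (data frame `scaffold`, `start`, `end`,
#'   `depth`), `expected` (per-bin data frame with `gc` and expected depth
#'   `mu`).
#' @export
simulate_depth <- function(genome, cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  skeleton <- bin_depth(data.frame(scaffold = character(), start = numeric(),
                                   end = numeric(), depth = numeric()),
                        genome$truth$scaffold_lengths,
                        bin_size = cfg$bin_size)
  skeleton <- annotate_gc(skeleton, genome$seqs)
  cr <- genome$truth$copy_ratio[skeleton$scaffold]
  g <- gc_bias_factor(skeleton$gc, cfg)
  g[is.na(g)] <- 1
  mu <- cfg$base_depth * as.numeric(cr) * g
  with_seed(seed, {
    depth <- stats::rnbinom(length(mu), size = cfg$nb_theta, mu = mu)
    intervals <- data.frame(scaffold = skeleton$scaffold,
                            start = skeleton$start, end = skeleton$end,
                            depth = depth, stringsAsFactors = FALSE)
    expected <- data.frame(scaffold = skeleton$scaffold,
                           start = skeleton$start, end = skeleton$end,
                           gc = skeleton$gc, mu = mu,
                           stringsAsFactors = FALSE)
    list(intervals = intervals, expected = expected)
  })
}

#' Simulate a stand-alone set of GC-biased depth bins
#'
#' Bin-level shortcut used to exercise GC normalization at scale without
#' generating sequence: GC drawn uniformly over `gc_block_range`, depth one
#' negative-binomial draw per bin at `mu = base_depth * g(gc)`.
#'
#' @param n_bins number of bins.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A bins data frame (as from [annotate_gc()]) with a `mu` truth
#'   column.
#' @export
simulate_depth_bins <- function(n_bins, cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), n_bins >= 1)
  with_seed(seed, {
    gc <- stats::runif(n_bins, cfg$gc_block_range[1], cfg$gc_block_range[2])
    mu <- cfg$base_depth * gc_bias_factor(gc, cfg)
    starts <- (seq_len(n_bins) - 1) * cfg$bin_size
    data.frame(scaffold = "sim_bins", start = starts,
               end = starts + cfg$bin_size, span = cfg$bin_size,
               mean_depth = stats::rnbinom(n_bins, size = cfg$nb_theta,
                                           mu = mu),
               short = FALSE, gc = gc, mu = mu, stringsAsFactors = FALSE)
  })
}

#' Simulate a tblastn-style best-hit table for X-linked markers
#'
#' Each marker's true origin is the X with probability `p_x`, otherwise an
#' autosome with probability proportional to length. The true-origin hit
#' gets e-value `10^-U`, U ~ Uniform(20, 120); 0-`decoy_max` decoy hits to
#' random scaffolds get e-values at least 1000-fold weaker, so decoys never
#' outrank true hits under best-hit filtering.
#'
#' @param genome output of [simulate_genome()] (only lengths and the X
#'   identity are used).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list: `hits` (12-column outfmt-6 data frame) and `truth`
#'   (data frame `query`, `origin`).
#' @export
simulate_hits <- function(genome, cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  lens <- genome$truth$scaffold_lengths
  xsc <- genome$truth$x_scaffold
  auto <- setdiff(names(lens), xsc)
  with_seed(seed, {
    n <- cfg$n_markers
    queries <- sprintf("marker_%04d", seq_len(n))
    on_x <- stats::runif(n) < cfg$p_x
    origin <- character(n)
    origin[on_x] <- xsc
    if (any(!on_x)) {
      origin[!on_x] <- sample(auto, sum(!on_x), replace = TRUE,
                              prob = lens[auto] / sum(lens[auto]))
    }
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      best_e <- 10^(-stats::runif(1, 20, 120))
      best_bit <- round(60 + 1.8 * (-log10(best_e)) + stats::rnorm(1, 0, 5), 1)
      alen <- sample(80:300, 1)
      sstart <- sample.int(max(1, lens[origin[i]] - 3 * alen), 1)
      n_decoy <- sample.int(cfg$decoy_max + 1L, 1) - 1L
      r <- data.frame(
        query = queries[i],
        subject = c(origin[i], sample(names(lens), n_decoy, replace = TRUE)),
        pct_identity = round(stats::runif(1 + n_decoy, 35, 95), 1),
        aln_length = c(alen, sample(40:200, n_decoy, replace = TRUE)),
        mismatches = sample(0:80, 1 + n_decoy, replace = TRUE),
        gap_opens = sample(0:5, 1 + n_decoy, replace = TRUE),
        qstart = 1L, qend = c(alen, sample(40:200, n_decoy, replace = TRUE)),
        sstart = sstart, send = sstart + 3 * alen,
        evalue = c(best_e, best_e * 10^stats::runif(n_decoy, 3, 10)),
        bitscore = c(best_bit,
                     round(best_bit - stats::runif(n_decoy, 15, 50), 1)),
        stringsAsFactors = FALSE
      )
      rows[[i]] <- r
    }
    hits <- do.call(rbind, rows)
    rownames(hits) <- NULL
    list(hits = hits, truth = data.frame(query = queries, origin = origin,
                                         stringsAsFactors = FALSE))
  })
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Evolve amino-acid sequences along a tree under the equal-rates 20-state
# model: along a branch of length t (expected substitutions/site) each site
# is resampled uniformly from the 20 states with probability
# 1 - exp(-20 t / 19), giving P(same) = 1/20 + (19/20) exp(-20 t / 19).
sim_seqs_on_tree <- function(tree, n_sites) {
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")  # parents before children
  states <- vector("list", max(tree$edge))
  root <- ntip + 1L
  states[[root]] <- sample.int(20L, n_sites, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    ch <- states[[parent]]
    resample <- stats::runif(n_sites) < (1 - exp(-20 * t / 19))
    if (any(resample)) {
      ch[resample] <- sample.int(20L, sum(resample), replace = TRUE)
    }
    states[[child]] <- ch
  }
  stats::setNames(vapply(seq_len(ntip), function(i) {
    paste(AA_ALPHABET[states[[i]]], collapse = "")
  }, character(1)), tree$tip.label)
}

tips_of_node <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else ape::extract.clade(tree, node)$tip.label
}

# Regraft the taxa in `s` as a clade attached by an internal edge of
# length delta: the deep-duplication signature of paralogous gene copies.
inject_paralog_clade <- function(base_tree, s, delta) {
  backbone <- ape::drop.tip(base_tree, s)
  sub <- ape::keep.tip(base_tree, s)
  sub$root.edge <- delta
  ntip_b <- length(backbone$tip.label)
  where <- sample((ntip_b + 1L):(ntip_b + backbone$Nnode), 1L)
  ape::bind.tree(backbone, sub, where = where)
}

#' Simulate per-locus amino-acid alignments with injected paralogs
#'
#' A base tree over `n_taxa` taxa is drawn once (uniform branch lengths
#' over `edge_length_range`); its non-trivial clades stand in for the
#' published reference phylogeny. Sequences evolve under the equal-rates
#' 20-state model. Each locus independently drops each taxon with
#' probability `dropout_q` (always keeping at least 3). Designated paralog
#' loci evolve on a tree in which a taxon subset is regrafted as a clade on
#' an internal edge of length `paralog_delta_mult` times the base-tree
#' height — a deep duplication. The subset must straddle some reference
#' clade (at least two members regrafted and two left behind) and carry at
#' least one taxon from outside it, so the clade is genuinely split in the
#' gene tree.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list: `loci` (list of `locus_msa`), `truth` (data frame
#'   `locus_id`, `paralog`), `base_tree`, `reference_groups`, `full_taxa`.
#' @export
simulate_loci <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_taxa >= 6)
  with_seed(seed, {
    brfun <- function(n) stats::runif(n, cfg$edge_length_range[1],
                                      cfg$edge_length_range[2])
    base <- ape::rtree(cfg$n_taxa, br = brfun)
    base$tip.label <- sprintf("T%02d", as.integer(sub("t", "",
                                                      base$tip.label)))
    # the "published phylogeny": every non-trivial clade of the base tree
    root <- cfg$n_taxa + 1L
    nodes <- setdiff((cfg$n_taxa + 1L):(cfg$n_taxa + base$Nnode), root)
    groups <- lapply(nodes, function(k) sort(tips_of_node(base, k)))
    groups <- groups[lengths(groups) >= 2 &
                       lengths(groups) <= cfg$n_taxa - 2L]
    names(groups) <- sprintf("clade_%d", seq_along(groups))
    full_taxa <- sort(base$tip.label)
    height <- max(ape::node.depth.edgelength(base)[seq_len(cfg$n_taxa)])
    delta <- cfg$paralog_delta_mult * height
    n_par <- round(cfg$paralog_frac * cfg$n_loci)
    is_par <- rep(FALSE, cfg$n_loci)
    if (n_par > 0) is_par[sample.int(cfg$n_loci, n_par)] <- TRUE
    loci <- vector("list", cfg$n_loci)
    for (l in seq_len(cfg$n_loci)) {
      tree_l <- base
      if (is_par[l]) {
        repeat {
          s <- full_taxa[stats::runif(cfg$n_taxa) < 0.35]
          if (length(s) < 2L || length(s) > cfg$n_taxa - 3L) next
          # the duplication must split some published clade: at least two
          # members regrafted, two left behind, and the regrafted clade
          # must carry an outside taxon so no single edge can reunite them
          straddles <- vapply(groups, function(g) {
            sum(g %in% s) >= 2 && sum(!g %in% s) >= 2 && !all(s %in% g)
          }, logical(1))
          if (any(straddles)) break
        }
        tree_l <- inject_paralog_clade(base, s, delta)
      }
      seqs <- sim_seqs_on_tree(tree_l, cfg$n_sites)
      keep <- names(seqs)[stats::runif(length(seqs)) >= cfg$dropout_q]
      if (length(keep) < 3L) keep <- sample(names(seqs), 3L)
      loci[[l]] <- new_msa(sprintf("locus_%04d", l), seqs[sort(keep)])
    }
    list(loci = loci,
         truth = data.frame(locus_id = sprintf("locus_%04d",
                                               seq_len(cfg$n_loci)),
                            paralog = is_par, stringsAsFactors = FALSE),
         base_tree = base, reference_groups = groups, full_taxa = full_taxa)
  })
}

#' Simulate a GFF3 annotation with known intron lengths
#'
#' Transcripts are placed on scaffolds with probability proportional to
#' length; each has `1 + Geometric(exon_geom_p)` exons with log-normal
#' exon and intron lengths (configured medians and sdlog). A transcript
#' that cannot fit on its scaffold is resampled (error after 100 attempts).
#'
#' @param genome output of [simulate_genome()] (only lengths are used), or
#'   a list with `truth$scaffold_lengths`.
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return A list: `features` (data frame as from [read_gff3()]) and
#'   `truth` (named list transcript id -> integer intron lengths).
#' @export
simulate_annotation <- function(genome, cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  lens <- genome$truth$scaffold_lengths
  with_seed(seed, {
    rows <- list()
    truth <- list()
    for (i in seq_len(cfg$n_transcripts)) {
      tid <- sprintf("t%04d", i)
      gid <- sprintf("g%04d", i)
      sc <- sample(names(lens), 1, prob = lens / sum(lens))
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        n_ex <- 1L + stats::rgeom(1, cfg$exon_geom_p)
        ex_len <- pmax(round(stats::rlnorm(n_ex, log(cfg$exon_median),
                                           cfg$exon_sdlog)), 10)
        in_len <- if (n_ex > 1L) {
          pmax(round(stats::rlnorm(n_ex - 1L, log(cfg$intron_median),
                                   cfg$intron_sdlog)), 1)
        } else integer(0)
        span <- sum(ex_len) + sum(in_len)
        if (span <= lens[sc]) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stopf("transcript %s does not fit on scaffold %s", tid, sc)
      start <- sample.int(lens[sc] - span + 1L, 1)
      ex_starts <- start + cumsum(c(0, (ex_len + c(in_len, 0))[-n_ex]))
      ex_ends <- ex_starts + ex_len - 1L
      strand <- sample(c("+", "-"), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold = sc, source = "sim",
        type = c("gene", "mRNA", rep("exon", n_ex)),
        start = c(start, start, ex_starts),
        end = c(start + span - 1L, start + span - 1L, ex_ends),
        score = NA_real_, strand = strand, phase = ".",
        ID = c(gid, tid, rep(NA_character_, n_ex)),
        Parent = c(NA_character_, gid, rep(tid, n_ex)),
        attributes = c(sprintf("ID=%s", gid),
                       sprintf("ID=%s;Parent=%s", tid, gid),
                       rep(sprintf("Parent=%s", tid), n_ex)),
        stringsAsFactors = FALSE
      )
      truth[[tid]] <- as.integer(in_len)
    }
    features <- do.call(rbind, rows)
    rownames(features) <- NULL
    list(features = features, truth = truth[order(names(truth))])
  })
}

#' Write annotation features as GFF3
#'
#' @param features data frame with the columns of [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     features$scaffold, features$source, features$type,
                     as.integer(features$start), as.integer(features$end),
                     ifelse(is.na(features$score), ".",
                            as.character(features$score)),
                     features$strand, features$phase, features$attributes),
             con)
  invisible(path)
}

#' Simulate the full study input bundle
#'
#' Chains [simulate_genome()], [simulate_depth()], [simulate_hits()],
#' [simulate_annotation()] and optionally [simulate_loci()], deriving one
#' sub-seed per generator from `seed`. When `dir` is given, writes
#' `genome.fasta`, `depth.bed`, `hits.tsv`, `annotation.gff3`,
#' `loci/<id>.fasta` and `truth.json` there.
#'
#' @param cfg a [sim_config()].
#' @param seed master integer seed.
#' @param dir output directory, or `NULL` to keep everything in memory.
#' @param include_loci also simulate the per-locus alignments.
#' @return A list: `genome`, `depth`, `hits`, `annotation`, `loci`
#'   (or `NULL`), `truth` (merged ground-truth list), `seed`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1, dir = NULL,
                           include_loci = FALSE) {
  seeds <- derive_seeds(seed, 5L)
  genome <- simulate_genome(cfg, seeds[1])
  depth <- simulate_depth(genome, cfg, seeds[2])
  hits <- simulate_hits(genome, cfg, seeds[3])
  annotation <- simulate_annotation(genome, cfg, seeds[4])
  loci <- if (include_loci) simulate_loci(cfg, seeds[5]) else NULL
  truth <- list(
    seed = seed,
    x_scaffold = genome$truth$x_scaffold,
    scaffold_lengths = as.list(genome$truth$scaffold_lengths),
    copy_ratio = as.list(genome$truth$copy_ratio),
    marker_origin = stats::setNames(as.list(hits$truth$origin),
                                    hits$truth$query),
    intron_lengths = annotation$truth,
    paralog_loci = if (include_loci) {
      loci$truth$locus_id[loci$truth$paralog]
    } else NULL,
    reference_groups = if (include_loci) loci$reference_groups else NULL
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome$seqs, file.path(dir, "genome.fasta"))
    write_depth_bed(depth$intervals, file.path(dir, "depth.bed"))
    utils::write.table(hits$hits, file.path(dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_gff3(annotation$features, file.path(dir, "annotation.gff3"))
    if (include_loci) {
      dir.create(file.path(dir, "loci"), showWarnings = FALSE)
      for (msa in loci$loci) {
        write_msa_fasta(msa, file.path(dir, "loci",
                                       paste0(msa$locus_id, ".fasta")))
      }
      writeLines(loci$full_taxa, file.path(dir, "taxa.txt"))
    }
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(genome = genome, depth = depth, hits = hits, annotation = annotation,
       loci = loci, truth = truth, seed = seed)
}
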