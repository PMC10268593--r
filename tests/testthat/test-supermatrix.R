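msa_of <- function(id = "L1", ...) {
  new_msa(id, unlist(list(...)))
}

test_that("high-missingness taxa are removed against the per-locus maximum", {
  msa <- msa_of("L1",
                A = paste(rep("K", 100), collapse = ""),
                B = paste(c(rep("K", 40), rep("-", 60)), collapse = ""))
  out <- filter_taxa(msa)
  expect_equal(names(out$msa$seqs), "A")
  expect_equal(out$occupancy$fraction_missing, c(0, 0.6))

  msa <- msa_of("L2", A = "KKKK", B = "KKKK")
  out <- filter_taxa(msa)
  expect_equal(length(out$msa$seqs), 2L)
  expect_equal(out$occupancy$fraction_missing, c(0, 0))

  # exactly 50% missing is retained (strict >)
  msa <- msa_of("L3",
                A = paste(rep("K", 100), collapse = ""),
                B = paste(c(rep("K", 50), rep("?", 50)), collapse = ""))
  expect_equal(length(filter_taxa(msa)$msa$seqs), 2L)

  msa <- msa_of("L4", A = "----", B = "KKKK")
  expect_equal(names(filter_taxa(msa)$msa$seqs), "B")
})

test_that("occupancy filter enforces the strict threshold and required taxon", {
  full <- sprintf("T%02d", 1:10)
  mk <- function(taxa) {
    new_msa(paste(taxa, collapse = ""),
            setNames(rep("KKKKK", length(taxa)), taxa))
  }
  nine <- mk(full[1:9])                  # 0.9 > 0.8, includes T01
  eight <- mk(full[1:8])                 # 0.8 is not > 0.8
  nine_noreq <- mk(full[2:10])           # 0.9 but missing required T01
  out <- locus_occupancy_filter(list(nine, eight, nine_noreq), full,
                                required_taxon = "T01")
  expect_equal(out$report$kept, c(TRUE, FALSE, FALSE))
  expect_equal(length(out$kept), 1L)
})

test_that("p-distances use jointly non-missing sites and respect min_overlap", {
  msa <- msa_of("L1", A = "KKKKKKKKKK", B = "KKKKKRRRRR", C = "RRRRR-----")
  d <- pdistance_matrix(msa, min_overlap = 5)
  expect_equal(d["A", "B"], 0.5)
  expect_equal(d["A", "C"], 1.0)
  expect_equal(d["B", "C"], 1.0)   # 5 joint sites, all differ
  expect_error(pdistance_matrix(msa, min_overlap = 6), "share only 5")
})

test_that("NJ resolves the worked 4-taxon additive matrix as AB|CD", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_from_dist(D)
  sp <- oracle_tree_splits(tr)
  expect_equal(length(sp), 1L)
  expect_equal(sp[[1]], c("C", "D"))   # canonical side excludes A: AB|CD
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1, tolerance = 1e-9)
  # terminal branches from the three-point closed forms
  tb <- hemiscan:::terminal_branch_lengths(tr)
  expect_equal(tb[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4),
               tolerance = 1e-9)
})

test_that("NJ handles 3 taxa and identical sequences", {
  msa <- msa_of("L1", A = strrep("K", 30), B = strrep("K", 30),
                C = strrep("K", 30))
  tr <- nj_tree(msa)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sum(tr$edge.length), 0)

  # forced 3-taxon topology with closed-form lengths:
  # d(A,B)=0.2, d(A,C)=0.4, d(B,C)=0.4 -> a=0.1, b=0.1, c=0.3
  D <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_from_dist(D)
  tb <- hemiscan:::terminal_branch_lengths(tr)
  expect_equal(tb[c("A", "B", "C")], c(A = .1, B = .1, C = .3),
               tolerance = 1e-9)
  expect_error(nj_tree(msa_of("L2", A = "KK", B = "KK")), "at least 3")
})

test_that("NJ recovers random additive trees exactly", {
  for (i in 1:30) {
    n <- sample(4:8, 1)
    ad <- random_additive_tree(n, 5000 + i)
    tr <- nj_from_dist(ad$D)
    expect_equal(ape::dist.topo(ape::unroot(ad$tree), tr), 0,
                 ignore_attr = TRUE)
    # and reproduces the metric, not just the topology
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ad$D), colnames(ad$D)],
                 ad$D, tolerance = 1e-8)
  }
})

test_that("branch-outlier flags need both the fold rule and the floor", {
  tr <- read_newick(paste0("(", paste(sprintf("t%d:0.01", 1:9), collapse = ","),
                           ",x:0.5);"))
  expect_equal(flag_branch_outliers(tr), "x")
  tr <- read_newick("(a:0.1,b:0.1,c:0.1,d:0.1);")
  expect_equal(flag_branch_outliers(tr), character(0))
  # below the absolute floor: never flagged
  tr <- read_newick("(a:0.005,b:0.005,c:0.005,d:0.04);")
  expect_equal(flag_branch_outliers(tr), character(0))
})

test_that("paralog flag needs a split reference group and a dominant edge", {
  # group {A,B} split by an internal edge of length 10 (total length 15)
  tr <- read_newick("((A:1,C:1):10,(B:1,D:1):1);")
  out <- flag_paralogs(tr, list(g1 = c("A", "B")))
  expect_true(out$flag)
  expect_equal(out$group, "g1")
  expect_gte(out$edge_length, 0.2 * out$total_length)

  # all groups monophyletic: never flagged, whatever the edge lengths
  tr <- read_newick("((A:1,B:1):10,(C:1,D:1):1);")
  expect_false(flag_paralogs(tr, list(g1 = c("A", "B"),
                                      g2 = c("C", "D")))$flag)

  # split group, but only short internal edges: not flagged
  tr <- read_newick("((A:10,C:10):0.5,(B:10,D:10):0.5);")
  expect_false(flag_paralogs(tr, list(g1 = c("A", "B")))$flag)

  # group members absent from the tree are ignored; < 2 present skips
  tr <- read_newick("((A:1,C:1):10,(B:1,D:1):1);")
  expect_false(flag_paralogs(tr, list(g1 = c("A", "Z")))$flag)
})

test_that("concatenation bookkeeping matches the padding arithmetic", {
  l1 <- msa_of("locus_a", A = "KKKKK", B = "RRRRR")
  l2 <- msa_of("locus_b", A = "DDDDDDD", C = "EEEEEEE")
  sm <- concatenate_loci(list(l1, l2), c("A", "B", "C"))
  expect_equal(nchar(sm$seqs[["A"]]), 12L)
  expect_equal(sm$partitions$start, c(1, 6))
  expect_equal(sm$partitions$end, c(5, 12))
  expect_equal(sm$missing_fraction[["A"]], 0)
  expect_equal(sm$missing_fraction[["B"]], 7 / 12)
  expect_equal(sm$missing_fraction[["C"]], 5 / 12)
  expect_equal(sm$seqs[["B"]], "RRRRR-------")

  # single locus with full taxa: missingness equals the in-locus gaps
  l3 <- msa_of("locus_c", A = "KK-?", B = "KKKK")
  sm <- concatenate_loci(list(l3), c("A", "B"))
  expect_equal(sm$missing_fraction[["A"]], 0.5)
  expect_error(concatenate_loci(list(), c("A")), "no loci")
  expect_error(concatenate_loci(list(l1, l1), c("A", "B")), "duplicate locus")
})

test_that("NEXUS round trip reproduces matrix, partitions and missingness", {
  l1 <- msa_of("locus_a", A = "KKKKK", B = "RR-RR")
  l2 <- msa_of("locus_b", A = "DDDDDDD", C = "EEE?EEE")
  sm <- concatenate_loci(list(l1, l2), c("A", "B", "C"))
  f <- tempfile(fileext = ".nex")
  write_nexus_supermatrix(sm, f)
  back <- read_nexus_supermatrix(f)
  expect_equal(back$seqs, sm$seqs)
  expect_equal(back$partitions, sm$partitions)
  expect_equal(back$missing_fraction, sm$missing_fraction, tolerance = 1e-9)
  expect_equal(sum(back$partitions$end - back$partitions$start + 1),
               nchar(back$seqs[[1]]))

  fp <- tempfile(fileext = ".phy")
  write_phylip_supermatrix(sm, fp)
  hdr <- strsplit(readLines(fp, n = 1), " ")[[1]]
  expect_equal(as.integer(hdr), c(3L, 12L))
  fr <- tempfile(fileext = ".part")
  write_raxml_partitions(sm, fr)
  expect_match(readLines(fr)[1], "WAG, locus_a = 1-5")
})

test_that("the full curation chain keeps clean loci and drops paralogs", {
  cfg <- sim_config(n_loci = 30, dropout_q = 0.05)
  sl <- simulate_loci(cfg, 909)
  cur <- curate_loci(sl$loci, sl$full_taxa, required_taxon = sl$full_taxa[1],
                     reference_groups = sl$reference_groups)
  rep <- merge(cur$report, sl$truth, by = "locus_id")
  # paralog loci overwhelmingly dropped, clean loci overwhelmingly kept
  expect_lt(mean(rep$retained[rep$paralog]), 0.2)
  expect_gt(mean(rep$retained[!rep$paralog]), 0.6)
  expect_s3_class(cur$supermatrix, "supermatrix")
  expect_equal(sum(with(cur$supermatrix$partitions, end - start + 1)),
               nchar(cur$supermatrix$seqs[[1]]))
})

test_that("curation decisions are independent of locus and row order", {
  cfg <- sim_config(n_loci = 12, dropout_q = 0.1)
  sl <- simulate_loci(cfg, 303)
  base <- curate_loci(sl$loci, sl$full_taxa, required_taxon = sl$full_taxa[1],
                      reference_groups = sl$reference_groups)
  set.seed(1)
  perm <- sample(seq_along(sl$loci))
  shuffled <- lapply(sl$loci[perm], function(m) {
    new_msa(m$locus_id, m$seqs[sample(seq_along(m$seqs))])
  })
  again <- curate_loci(shuffled, sl$full_taxa,
                       required_taxon = sl$full_taxa[1],
                       reference_groups = sl$reference_groups)
  a <- base$report[order(base$report$locus_id), ]
  b <- again$report[order(again$report$locus_id), ]
  expect_equal(a$retained, b$retained)
  expect_equal(a$paralog_flag, b$paralog_flag)
})
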