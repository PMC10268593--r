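tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("FASTA reading folds lines, uppercases, and validates", {
  f <- tmp_file(c(">s1", "ACGT"))
  expect_equal(read_fasta(f), c(s1 = "ACGT"))

  f <- tmp_file(c(">a desc", "ac", "gt", ">b", "NNNN"))
  seqs <- read_fasta(f)
  expect_equal(names(seqs), c("a", "b"))
  expect_equal(unname(nchar(seqs)), c(4L, 4L))
  expect_equal(seqs[["a"]], "ACGT")

  expect_error(read_fasta(tmp_file(c(">a", ">a", "AC"))),
               "duplicate|empty")
  expect_error(read_fasta(tmp_file(c("ACGT"))), "begin with")
  expect_error(read_fasta(tmp_file(c(">a", "ACGR"))), "outside")
  # amino-acid content allowed when alphabet is relaxed
  expect_silent(read_fasta(tmp_file(c(">a", "MKL-")), alphabet = "any"))
})

test_that("FASTA write/read round-trips random sequences", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    seqs <- setNames(
      vapply(seq_len(n), function(j) {
        paste(sample(c("A", "C", "G", "T", "N"), sample(1:200, 1),
                     replace = TRUE), collapse = "")
      }, character(1)),
      paste0("seq", seq_len(n)))
    f <- tempfile(fileext = ".fasta")
    write_fasta(seqs, f)
    expect_equal(read_fasta(f), seqs)
  }
})

test_that("depth BED parsing sorts, validates, and round-trips", {
  f <- tmp_file("s1\t0\t100\t7")
  iv <- read_depth_bed(f)
  expect_equal(iv$start, 0)
  expect_equal(iv$end, 100)
  expect_equal(iv$depth, 7)

  f <- tmp_file(c("s2\t0\t10\t1", "s1\t50\t60\t2", "s1\t0\t10\t3"))
  iv <- read_depth_bed(f)
  expect_equal(iv$scaffold, c("s1", "s1", "s2"))
  expect_equal(iv$start, c(0, 50, 0))

  expect_error(read_depth_bed(tmp_file("s1\t50\t50\t3")), "start")
  expect_error(read_depth_bed(tmp_file("s1\t0\t10\t-1")), "negative depth")
  expect_error(read_depth_bed(tmp_file(c("s1\t0\t10\t1", "s1\t0\t10"))),
               "line 2")

  iv <- data.frame(scaffold = "sA", start = c(0, 10), end = c(10, 25),
                   depth = c(3, 0.5))
  f <- tempfile()
  write_depth_bed(iv, f)
  expect_equal(read_depth_bed(f), iv)
})

test_that("outfmt-6 hit tables parse with located errors", {
  f <- tmp_file("g1\ts4\t88.2\t300\t30\t2\t1\t300\t500\t1399\t1e-50\t400")
  h <- read_hits_tsv(f)
  expect_equal(h$evalue, 1e-50)
  expect_equal(h$subject, "s4")
  expect_equal(h$bitscore, 400)

  f <- tmp_file(c("# tblastn",
                  "g1\ts4\t88.2\t300\t30\t2\t1\t300\t500\t1399\t1e-50\t400"))
  expect_equal(nrow(read_hits_tsv(f)), 1L)

  f <- tmp_file(c("g1\ts4\t88.2\t300\t30\t2\t1\t300\t500\t1399\t1e-50\t400",
                  "g2\ts4\t88.2\t300\t30\t2\t1\t300\t500\t1399\t1e-50"))
  expect_error(read_hits_tsv(f), "line 2.*11 columns")
})

test_that("GFF3 parsing keeps 1-based coordinates and attributes", {
  f <- tmp_file(c("##gff-version 3", "s1\tx\texon\t1\t100\t.\t+\t.\tParent=t1"))
  g <- read_gff3(f)
  expect_equal(nrow(g), 1L)
  expect_equal(g$start, 1L)
  expect_equal(g$end, 100L)
  expect_equal(g$Parent, "t1")

  expect_error(read_gff3(tmp_file("s1\tx\texon\t200\t100\t.\t+\t.\tID=e1")),
               "start 200 > end 100")
  expect_error(read_gff3(tmp_file("s1\tx\texon\t1\t100\t.\t+\t.")),
               "8 columns")
})

test_that("aligned FASTA enforces equal row lengths", {
  f <- tmp_file(c(">A", "MK-", ">B", "MKL"), ext = ".fasta")
  msa <- read_msa_fasta(f)
  expect_s3_class(msa, "locus_msa")
  expect_equal(length(msa$seqs), 2L)
  expect_equal(nchar(msa$seqs[["A"]]), 3L)
  expect_equal(msa$seqs[["A"]], "MK-")

  expect_error(read_msa_fasta(tmp_file(c(">A", "MK", ">B", "MKL"))), "ragged")
  f <- tempfile(); file.create(f)
  expect_error(read_msa_fasta(f))
})

test_that("Newick parse and write round-trip to 10 significant digits", {
  tr <- read_newick("(A:1,B:2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))

  txt <- "((A:1,B:2):0.5,C:3);"
  expect_equal(write_newick(read_newick(txt)), txt)
  expect_error(read_newick("(A:1,B:2)"), "terminal ';'")

  set.seed(5)
  for (i in 1:10) {
    tr <- ape::rtree(sample(3:12, 1))
    tr$edge.length <- round(runif(length(tr$edge.length), 0.001, 2), 6)
    back <- read_newick(write_newick(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("readers reject corrupted lines and accept valid ones (fuzz)", {
  set.seed(42)
  n_ok <- 0
  for (i in 1:250) {
    sc <- sample(c("s1", "s2", "chr_9"), 1)
    a <- sample.int(1e6, 1)
    b <- a + sample.int(1e4, 1)
    good <- sprintf("%s\t%d\t%d\t%g", sc, a, b, runif(1, 0, 100))
    expect_equal(nrow(read_depth_bed(tmp_file(good))), 1L)
    n_ok <- n_ok + 1
    corrupt <- switch(sample.int(4, 1),
                      sprintf("%s\t%d\t%d", sc, a, b),              # 3 cols
                      sprintf("%s\t%d\t%d\t-2", sc, a, b),          # neg depth
                      sprintf("%s\t%d\t%d\t5", sc, b, a),           # inverted
                      sprintf("%s\t%d\t%d\tdeep", sc, a, b))        # non-numeric
    expect_error(read_depth_bed(tmp_file(corrupt)))
  }
  expect_equal(n_ok, 250)
})

test_that("SAM alignments convert to depth intervals under the filters", {
  sam <- c("@HD\tVN:1.6",
           "@SQ\tSN:s1\tLN:50",
           # primary, mapq 60, 10M: covers 1..10 (0-based 0..10)
           "r1\t0\ts1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
           # primary, mapq 60, 5M5D5M: M covers 11..15 and 21..25
           "r2\t0\ts1\t11\t60\t5M5D5M\t*\t0\t0\tACGTAACGTA\t*",
           # secondary alignment: skipped
           "r3\t256\ts1\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
           # low mapq: skipped at min_mapq = 10
           "r4\t0\ts1\t30\t5\t10M\t*\t0\t0\tACGTACGTAC\t*")
  f <- tmp_file(sam, ext = ".sam")
  iv <- sam_to_depth(f, min_mapq = 10)
  # r1 covers [0,10), r2's M ops cover [10,15) and [20,25); adjacent
  # equal-depth runs merge
  expect_equal(iv$depth, c(1, 1))
  expect_equal(iv$start, c(0, 20))
  expect_equal(iv$end, c(15, 25))
  # without the mapq filter r4 contributes
  iv2 <- sam_to_depth(f, min_mapq = 0)
  expect_true(any(iv2$start == 29))
})
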