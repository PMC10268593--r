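test_that("binning computes overlap-weighted means and flags partial bins", {
  iv <- data.frame(scaffold = "s1", start = 0, end = 25000, depth = 7)
  bins <- bin_depth(iv, c(s1 = 25000), bin_size = 10000)
  expect_equal(bins$mean_depth, c(7, 7, 7))
  expect_equal(bins$span, c(10000, 10000, 5000))
  expect_equal(bins$short, c(FALSE, FALSE, TRUE))

  iv <- data.frame(scaffold = "s1", start = 0, end = 5000, depth = 10)
  bins <- bin_depth(iv, c(s1 = 10000), bin_size = 10000)
  expect_equal(bins$mean_depth, 5.0)

  bins <- bin_depth(data.frame(scaffold = character(), start = numeric(),
                               end = numeric(), depth = numeric()),
                    c(s1 = 10000), bin_size = 10000)
  expect_equal(bins$mean_depth, 0)

  iv <- data.frame(scaffold = "s1", start = 0, end = 20000, depth = 1)
  expect_error(bin_depth(iv, c(s1 = 15000)), "beyond scaffold length")
  iv <- data.frame(scaffold = "s1", start = c(0, 500), end = c(1000, 1500),
                   depth = 1)
  expect_error(bin_depth(iv, c(s1 = 10000)), "overlap")
})

test_that("binning equals a per-base accumulation oracle on random intervals", {
  set.seed(21)
  for (rep in 1:20) {
    L <- sample(2000:8000, 1)
    bs <- sample(c(500, 1000, 1300), 1)
    # random non-overlapping intervals
    cuts <- sort(sample(0:L, sample(4:12, 1), replace = FALSE))
    cuts <- unique(c(0, cuts, L))
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1]
    keep <- runif(length(starts)) < 0.7
    iv <- data.frame(scaffold = "s", start = starts[keep], end = ends[keep],
                     depth = sample(0:50, sum(keep), replace = TRUE))
    perbase <- numeric(L)
    for (r in seq_len(nrow(iv))) {
      perbase[(iv$start[r] + 1):iv$end[r]] <- iv$depth[r]
    }
    bins <- bin_depth(iv, c(s = L), bin_size = bs)
    for (b in seq_len(nrow(bins))) {
      expect_equal(bins$mean_depth[b],
                   mean(perbase[(bins$start[b] + 1):bins$end[b]]))
    }
  }
})

test_that("GC annotation handles plain, all-N and pure-GC windows", {
  seqs <- c(s1 = paste0(strrep("ATGC", 2500), strrep("N", 10000),
                        strrep("G", 10000)))
  bins <- bin_depth(data.frame(scaffold = character(), start = numeric(),
                               end = numeric(), depth = numeric()),
                    c(s1 = 30000), bin_size = 10000)
  bins <- annotate_gc(bins, seqs)
  expect_equal(bins$gc, c(0.5, NA, 1.0))
})

test_that("stratified median-ratio normalization matches closed forms", {
  # single stratum: identity
  bins <- data.frame(scaffold = "s", start = 0:9 * 100, end = 1:10 * 100,
                     span = 100, mean_depth = c(8, 9, 10, 11, 12, 8, 9, 10, 11, 12),
                     short = FALSE, gc = 0.42)
  out <- gc_normalize(bins, min_bins = 1)
  expect_equal(out$bins$norm_depth, bins$mean_depth)

  # two equal strata with depths 10 and 20 -> everything at the global median 15
  bins <- data.frame(scaffold = "s", start = 0:19, end = 1:20, span = 1,
                     short = FALSE,
                     mean_depth = rep(c(10, 20), each = 10),
                     gc = rep(c(0.30, 0.50), each = 10))
  out <- gc_normalize(bins, min_bins = 5)
  expect_equal(out$bins$norm_depth, rep(15, 20))
  expect_equal(out$model$global_median, 15)

  # bins without GC stay unnormalized
  bins$gc[1] <- NA
  out <- gc_normalize(bins, min_bins = 5)
  expect_true(is.na(out$bins$norm_depth[1]))
  expect_error(gc_normalize(transform(bins, gc = NA_real_)), "no bins")
})

test_that("normalization flattens a simulated GC bias and conserves the median", {
  bins <- simulate_depth_bins(10000, sim_config(), seed = 314)
  # the raw bias is real: mean depth tracks g(gc)
  expect_gt(cor(tapply(bins$mean_depth, round(bins$gc, 2), mean),
                tapply(bins$mu, round(bins$gc, 2), mean)), 0.5)
  out <- gc_normalize(bins)
  ok <- !is.na(out$bins$norm_depth)
  rho <- suppressWarnings(
    cor(out$bins$norm_depth[ok], out$bins$gc[ok], method = "spearman"))
  expect_lt(abs(rho), 0.05)
  expect_lt(abs(median(out$bins$norm_depth[ok]) / out$model$global_median - 1),
            0.01)
  expect_true(all(out$bins$norm_depth[ok] >= 0))
})

test_that("scaffold summaries use interpolated central-95% percentiles", {
  mk <- function(v, sc = "s") {
    data.frame(scaffold = sc, start = seq_along(v), end = seq_along(v) + 1,
               span = 1, mean_depth = v, short = FALSE, gc = 0.4,
               norm_depth = v)
  }
  s <- summarize_scaffolds(mk(rep(30, 60)), min_bins_per_scaffold = 50)
  expect_equal(s$median_norm, 30)
  expect_equal(s$lo95, 30)
  expect_equal(s$hi95, 30)

  s <- summarize_scaffolds(mk(1:100), min_bins_per_scaffold = 50)
  expect_equal(s$median_norm, 50.5)
  expect_equal(s$lo95, 3.475)
  expect_equal(s$hi95, 97.525)

  bins <- rbind(mk(1:100, "big"), mk(1:10, "small"))
  expect_warning(s <- summarize_scaffolds(bins, min_bins_per_scaffold = 50),
                 "small")
  expect_equal(s$scaffold, "big")
  expect_error(suppressWarnings(
    summarize_scaffolds(mk(1:10), min_bins_per_scaffold = 50)), "no scaffold")
})

test_that("copy-ratio classification uses a length-weighted reference", {
  s <- data.frame(scaffold = c("s1", "s2", "s3"), n_bins = c(300, 280, 50),
                  median_norm = c(30, 30, 15), lo95 = 0, hi95 = 40)
  calls <- classify_ploidy(s)
  expect_equal(calls$ratio[calls$scaffold == "s3"], 0.5)
  expect_equal(calls$label, c("diploid", "diploid", "hemizygous"))

  s$median_norm <- c(20, 20, 20)
  expect_equal(classify_ploidy(s)$label, rep("diploid", 3))

  s$median_norm <- c(30, 30, 21)   # ratio 0.7: in neither band
  expect_equal(classify_ploidy(s)$label[3], "ambiguous")
  expect_error(classify_ploidy(s[1, , drop = FALSE]), "at least 2")
})

test_that("classification is invariant to rescaling all depths", {
  set.seed(33)
  s <- data.frame(scaffold = paste0("s", 1:6),
                  n_bins = sample(50:300, 6),
                  median_norm = runif(6, 10, 40), lo95 = 0, hi95 = 50)
  base <- classify_ploidy(s)
  for (k in c(0.01, 3.7, 1e4)) {
    s2 <- transform(s, median_norm = median_norm * k)
    scaled <- classify_ploidy(s2)
    expect_equal(scaled$label, base$label)
    expect_equal(scaled$ratio, base$ratio, tolerance = 1e-12)
  }
})

test_that("the simulated X scaffold is recovered end to end", {
  cfg <- sim_config()
  for (i in 1:5) {
    seeds <- hemiscan:::derive_seeds(400 + i, 2)
    g <- simulate_genome(cfg, seeds[1])
    d <- simulate_depth(g, cfg, seeds[2])
    sc <- xscan(g$seqs, d$intervals)
    hemi <- sc$calls$scaffold[sc$calls$label == "hemizygous"]
    expect_equal(hemi, g$truth$x_scaffold)
    xr <- sc$calls$ratio[sc$calls$scaffold == g$truth$x_scaffold]
    expect_gt(xr, 0.35)
    expect_lt(xr, 0.65)
  }
})
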