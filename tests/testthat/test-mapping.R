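test_that("end-to-end alignment finds exact substrings on both strands", {
  ref <- random_dna_str(2000, 1)
  frag <- substr(ref, 38, 137)                 # 0-based start 37
  h <- align_end_to_end(frag, ref, fragment_id = "f1")
  expect_equal(h$start, 37L)
  expect_equal(h$end, 137L)
  expect_equal(h$strand, "+")
  expect_equal(h$n_mismatches, 0L)

  hm <- align_end_to_end(revcomp(frag), ref)
  expect_equal(hm$start, 37L)
  expect_equal(hm$strand, "-")

  # random fragment vs unrelated reference: best Hamming distance far
  # exceeds 10% of length, so no hit
  expect_null(align_end_to_end(random_dna_str(100, 2), ref))
  expect_error(align_end_to_end(random_dna_str(300, 3),
                                random_dna_str(100, 4)),
               "longer than reference")
})

test_that("mismatched fragments map to the best position within tolerance", {
  ref <- random_dna_str(1500, 5)
  frag <- mutate_k(substr(ref, 501, 700), 8, seed = 6)   # 4% divergent
  h <- align_end_to_end(frag, ref)
  expect_equal(h$start, 500L)
  expect_equal(h$n_mismatches, 8L)
  # above the 10% ceiling: rejected
  frag_bad <- mutate_k(substr(ref, 501, 700), 30, seed = 7)
  expect_null(align_end_to_end(frag_bad, ref))
  expect_lte(h$n_mismatches, ceiling(0.1 * 200))
})

test_that("self-mapping is perfect at zero divergence and zero error", {
  arr <- make_test_array(6, 0.05, seed = 8)
  fr <- simulate_fragments(arr, fragment_model(), 150, seed = 9)
  hits <- align_fragments(fr, array_sequence(arr), ref_name = arr$name)
  expect_equal(nrow(hits), 150L)
  expect_true(all(hits$n_mismatches == 0L))
  expect_equal(hits$start, fr$start[match(hits$fragment_id, fr$fragment_id)])
  expect_true(all(hits$end - hits$start ==
                    fr$length[match(hits$fragment_id, fr$fragment_id)]))
})

test_that("triplicated consensus has three period-spaced boxes", {
  u <- build_dimer()
  tri <- triplicate_consensus(u)
  expect_equal(nchar(tri), 1020L)
  expect_equal(nchar(triplicate_consensus(build_dimer(period = 342))), 1026L)
  hits <- scan_motifs(tri, max_mismatches = 0)
  expect_equal(nrow(hits), 3L)
  expect_equal(diff(hits$start), c(340L, 340L))
})

test_that("folding conserves mass and wraps junction-spanning hits", {
  p <- 340L
  # single 50-nt hit in the middle copy folds onto [10, 60)
  h1 <- data.frame(fragment_id = "a", ref_name = "t", start = p + 10L,
                   end = p + 60L, strand = "+", n_mismatches = 0L)
  f1 <- fold_to_middle_dimer(h1, p)
  expect_length(f1, p)
  expect_equal(sum(f1), 50)
  expect_equal(which(f1 == 1) - 1L, 10:59)

  # a hit spanning the copy junction wraps modulo the period
  h2 <- data.frame(fragment_id = "b", ref_name = "t", start = p - 20L,
                   end = p + 30L, strand = "+", n_mismatches = 0L)
  f2 <- fold_to_middle_dimer(h2, p)
  expect_equal(sum(f2), 50)
  expect_equal(which(f2 == 1) - 1L, c(0:29, (p - 20):(p - 1)))

  # uniform tiling of all three copies folds flat
  starts <- seq(0L, 3L * p - 10L, by = 10L)
  h3 <- data.frame(fragment_id = paste0("t", starts), ref_name = "t",
                   start = starts, end = starts + 10L, strand = "+",
                   n_mismatches = 0L)
  f3 <- fold_to_middle_dimer(h3, p)
  expect_true(all(f3 == f3[1]))
  expect_equal(sum(f3), sum(h3$end - h3$start))

  expect_error(fold_to_middle_dimer(
    data.frame(start = -1L, end = 10L), p), "outside")
  expect_error(fold_to_middle_dimer(
    data.frame(start = 0L, end = 3L * p + 1L), p), "outside")
})

test_that("folded profiles are invariant to alignment tie-breaking", {
  # on a homogeneous triplicated reference every fragment matches all three
  # copies equally well; folding must erase which copy the aligner picked
  u <- build_dimer()
  tri <- triplicate_consensus(u)
  arr <- evolve_array(u, 3, 0, seed = 1)
  arr$truth_occupancy <- rep(1, 3)
  fr <- simulate_fragments(arr, fragment_model(), 300, seed = 10)
  hits_l <- align_fragments(fr, tri, tie_break = "leftmost_plus")
  hits_r <- align_fragments(fr, tri, tie_break = "rightmost_minus")
  expect_false(identical(hits_l$start, hits_r$start))
  fold_l <- fold_to_middle_dimer(hits_l, 340L)
  fold_r <- fold_to_middle_dimer(hits_r, 340L)
  expect_equal(fold_l, fold_r)
  # and folding conserves the unfolded mass exactly
  expect_equal(sum(fold_l), sum(hits_l$end - hits_l$start))
})

test_that("tracks scale linearly with the calibration factor", {
  ref <- random_dna_str(400, 11)
  hits <- data.frame(fragment_id = c("a", "b"), ref_name = "r",
                     start = c(0L, 50L), end = c(100L, 150L),
                     strand = "+", n_mismatches = 0L)
  tr <- build_track(hits, ref)
  expect_s3_class(tr, "occupancy_track")
  expect_equal(tr$coverage[60], 2)
  expect_equal(tr$coverage[25], 1)
  expect_equal(tr$coverage[200], 0)
  expect_equal(sum(tr$coverage), sum(hits$end - hits$start))

  tr2 <- build_track(hits, ref, calibration_factor = 0.5)
  expect_equal(tr2$coverage, tr$coverage * 0.5)
  expect_equal(sum(tr2$coverage),
               0.5 * sum(hits$end - hits$start), tolerance = 1e-9)

  tr0 <- build_track(hits[0, ], ref)
  expect_true(all(tr0$coverage == 0))
  expect_error(build_track(hits, ref, calibration_factor = 0), "> 0")
})

test_that("bedGraph export round-trips the coverage", {
  ref <- random_dna_str(300, 12)
  hits <- data.frame(fragment_id = "a", ref_name = "arrX", start = 10L,
                     end = 110L, strand = "+", n_mismatches = 0L)
  tr <- build_track(hits, ref, calibration_factor = 2)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  cov <- numeric(300)
  for (i in seq_along(gr)) {
    cov[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- gr$score[i]
  }
  expect_equal(cov, tr$coverage)
})
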