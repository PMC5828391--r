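test_that("build_dimer constructs 340/342-nt units with a single box", {
  u <- build_dimer(box_offset = 60)
  expect_s3_class(u, "dimer_unit")
  expect_equal(nchar(u$sequence), 340L)
  expect_equal(substr(u$sequence, 61, 75), CENPB_BOX)

  mons <- default_monomers(340)
  u2 <- build_dimer(mons$monomer_a, mons$monomer_b, box_offset = 60)
  expect_equal(u2$sequence, u$sequence)

  u342 <- build_dimer(period = 342)
  expect_equal(nchar(u342$sequence), 342L)
  expect_equal(u342$period, 342L)

  # the written box is the only perfect occurrence on either strand
  md <- motif_density(u$sequence, max_mismatches = 0)
  expect_equal(md$n_hits, 1L)
})

test_that("build_dimer rejects bad offsets and bad characters", {
  expect_error(build_dimer(box_offset = 330), "out of range")
  expect_error(build_dimer(box_offset = -1), "out of range")
  expect_error(build_dimer(monomer_a = strrep("ACGTN", 34),
                           monomer_b = default_monomers(340)$monomer_b),
               "non-ACGT")
  expect_error(build_dimer(monomer_a = strrep("A", 100),
                           monomer_b = strrep("C", 100)),
               "340 or 342")
})

test_that("zero-divergence arrays are homogeneous with perfect boxes", {
  arr <- evolve_array(build_dimer(), 10, 0, seed = 7)
  seqs <- vapply(arr$units, `[[`, character(1), "sequence")
  expect_length(unique(seqs), 1L)
  expect_equal(arr$box_mismatches, rep(0L, 10))
  expect_equal(arr$box_scores, rep(1, 10))
  # exactly one box per dimer period
  md <- motif_density(array_sequence(arr))
  expect_equal(md$n_hits, 10L)
  expect_equal(md$density, 10 / 3.4)
})

test_that("divergence-rate sweep degrades boxes as the binomial tail predicts", {
  # rate 0.06: expected pairwise identity 100 * (1 - 2r(1-r) - 2r^2/3) = 88.5%
  arr <- evolve_array(build_dimer(), 50, 0.06, seed = 11)
  pid <- pairwise_identity(arr)
  off <- pid[upper.tri(pid)]
  expect_gt(mean(off), 86.5)
  expect_lt(mean(off), 90.5)
  expect_true(all(off >= 80 & off <= 98))

  # rate 0.25: P(>= 4 mismatches in 15 trials) = 1 - pbinom(3, 15, 0.25)
  # ~ 0.54, so about half the boxes are dead (score 0)
  arr25 <- evolve_array(build_dimer(), 200, 0.25, seed = 12)
  frac_dead <- mean(arr25$box_scores == 0)
  expect_gt(frac_dead, 0.40)
  expect_lt(frac_dead, 0.70)

  expect_error(evolve_array(build_dimer(), 10, 0.3), "0, 0.25")
  expect_error(evolve_array(build_dimer(), 0, 0.1), "n_units")
})

test_that("truth occupancy follows the link and weights shift with box score", {
  arr <- evolve_array(build_dimer(), 10, 0, seed = 1)
  # identity link, no noise: occupancy equals the box score exactly
  arr0 <- assign_truth_occupancy(arr, link = function(s) s, noise_sd = 0,
                                 seed = 1)
  expect_equal(arr0$truth_occupancy, arr$box_scores)
  # perfect boxes: high-salt weight at the strong-box endpoint
  expect_equal(unname(arr0$truth_fraction_weights[, "high_salt"]),
               rep(0.68, 10))
  expect_equal(rowSums(arr0$truth_fraction_weights), rep(1, 10),
               tolerance = 1e-12)

  # degraded arrays still have rows summing to one
  arrd <- assign_truth_occupancy(evolve_array(build_dimer(), 20, 0.2,
                                              seed = 3), seed = 4)
  expect_equal(rowSums(arrd$truth_fraction_weights), rep(1, 20),
               tolerance = 1e-12)

  expect_error(assign_truth_occupancy(arr, link = function(s) 1 - s),
               "monotone")
  expect_error(assign_truth_occupancy(arr, link = function(s) s - 0.5),
               "non-negative")
})

test_that("fragment counts track occupancy and lengths follow the mixture", {
  # one-unit array, dimeric-only model with zero sd: every fragment 340 nt
  one <- evolve_array(build_dimer(), 1, 0, seed = 1)
  one <- assign_truth_occupancy(one, noise_sd = 0, seed = 1)
  m340 <- fragment_model(c(subnucleosomal = 0, nucleosomal = 0, dimeric = 1),
                         sds = c(1, 1, 0))
  fr <- simulate_fragments(one, m340, 200, seed = 2, jitter_sd = 0)
  expect_true(all(fr$length == 340L))
  expect_true(all(fr$start == 0L))
  expect_equal(fr$sequence[1], array_sequence(one))

  # two units at 50:1 truth: count ratio within Poisson error of 50
  two <- evolve_array(build_dimer(), 2, 0.05, seed = 5)
  two$truth_occupancy <- c(1, 50)
  two$truth_fraction_weights <- matrix(0.25, 2, 4,
                                       dimnames = list(NULL, SALT_FRACTIONS))
  fr2 <- simulate_fragments(two, fragment_model(), 10200, seed = 6)
  counts <- table(factor(fr2$unit_index, levels = 1:2))
  expect_gt(counts[[2]] / counts[[1]], 39)
  expect_lt(counts[[2]] / counts[[1]], 61)

  # per-unit counts / occupancy flat within 3-sigma Poisson bands
  five <- evolve_array(build_dimer(), 5, 0, seed = 7)
  five$truth_occupancy <- c(1, 2, 3, 4, 5)
  five$truth_fraction_weights <- matrix(0.25, 5, 4,
                                        dimnames = list(NULL, SALT_FRACTIONS))
  fr5 <- simulate_fragments(five, fragment_model(), 15000, seed = 8)
  obs <- as.vector(table(factor(fr5$unit_index, levels = 1:5)))
  expected <- 15000 * five$truth_occupancy / sum(five$truth_occupancy)
  expect_true(all(abs(obs - expected) <= 3 * sqrt(expected)))

  # default mixture: modal bins at the nucleosomal and dimeric peaks
  arr <- make_test_array(10, 0.02, seed = 9)
  frd <- simulate_fragments(arr, fragment_model(), 6000, seed = 10)
  h <- length_histogram(frd$length, bin_width = 5)
  main_mode <- h$bin_start[which.max(h$count)]
  expect_gte(main_mode, 160); expect_lte(main_mode, 185)
  hi <- h[h$bin_start >= 300, ]
  minor_mode <- hi$bin_start[which.max(hi$count)]
  expect_gte(minor_mode, 330); expect_lte(minor_mode, 345)

  expect_error(simulate_fragments(evolve_array(build_dimer(), 2, 0),
                                  fragment_model(), 10),
               "occupancy")
})

test_that("emit_fastq writes truncated mates, spike-ins and a truth table", {
  td <- withr::local_tempdir()
  arr <- make_test_array(4, 0, seed = 1, noise_sd = 0)
  fr <- simulate_fragments(arr, fragment_model(), 50, seed = 3)
  # deterministic short fragment: mates truncated at the fragment end
  fr$length[1] <- 100L; fr$start[1] <- 0L
  fr$sequence[1] <- substr(array_sequence(arr), 1, 100)
  em <- emit_fastq(fr, read_length = 250, per_base_error = 0, seed = 4,
                   spike_in = list(genome = random_dna_str(2000, 5),
                                   n_reads = 1000),
                   out_dir = td, prefix = "t")
  pr <- read_fastq_pairs(em$r1, em$r2)
  expect_length(pr$seq1, 50 + 1000)
  expect_equal(sum(grepl("^spike\\|", pr$id)), 1000)
  i <- match(fr$fragment_id[1], pr$id)
  expect_equal(unname(nchar(pr$seq1[i])), 100L)
  expect_equal(unname(pr$seq2[i]), unname(revcomp(pr$seq1[i])))

  # 340-nt fragment at 2 x 250: mates overlap by 2*250 - 340 = 160 nt
  j <- which(fr$length == 340)[1]
  if (!is.na(j)) {
    m <- merge_pair(pr$seq1[j], pr$seq2[j])
    expect_equal(m$n_overlap, 160L)
  }

  truth <- read.delim(em$truth)
  expect_equal(nrow(truth), 50L)
  expect_identical(sort(names(truth)),
                   sort(c("fragment_id", "unit_index", "fraction", "length",
                          "start")))
  expect_error(emit_fastq(fr, read_length = 19), ">= 20")
})

test_that("identical seeds give byte-identical FASTQ output", {
  arr <- make_test_array(4, 0.05, seed = 1)
  fr <- simulate_fragments(arr, fragment_model(), 200, seed = 2)
  td1 <- withr::local_tempdir(); td2 <- withr::local_tempdir()
  spike <- list(genome = random_dna_str(1000, 9), n_reads = 40)
  e1 <- emit_fastq(fr, seed = 11, spike_in = spike, out_dir = td1)
  e2 <- emit_fastq(fr, seed = 11, spike_in = spike, out_dir = td2)
  expect_identical(unname(tools::md5sum(e1$r1)), unname(tools::md5sum(e2$r1)))
  expect_identical(unname(tools::md5sum(e1$r2)), unname(tools::md5sum(e2$r2)))
  e3 <- emit_fastq(fr, seed = 12, spike_in = spike, out_dir = td2)
  expect_false(identical(unname(tools::md5sum(e1$r1)),
                         unname(tools::md5sum(e3$r1))))
})
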