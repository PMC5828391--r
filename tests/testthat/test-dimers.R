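test_that("per-dimer statistics summarise flat and one-sided tracks", {
  arr <- evolve_array(build_dimer(), 4, 0, seed = 1)
  units <- unit_intervals(arr)
  flat <- rep(2, 4 * 340)
  prof <- per_dimer_occupancy(flat, units, box_starts(arr))
  expect_equal(prof$occupancy, rep(2, 4))
  expect_equal(prof$monomer_a_occ, prof$monomer_b_occ)
  # flat coverage: centroid at the unit midpoint, box at offset 60
  expect_equal(prof$centroid_offset, rep((340 - 1) / 2 - 60, 4))

  # coverage confined to monomer A of unit 2
  onea <- numeric(4 * 340)
  onea[(340 + 1):(340 + 170)] <- 5
  p2 <- per_dimer_occupancy(onea, units, box_starts(arr))
  expect_equal(p2$monomer_b_occ[2], 0)
  expect_gt(p2$monomer_a_occ[2], 0)
  expect_true(is.na(p2$centroid_offset[1]))    # unit 1 has no coverage

  expect_error(per_dimer_occupancy(flat[1:100], units), "bounds")
})

test_that("occupancy fold range matches its arithmetic contract", {
  expect_equal(occupancy_fold_range(c(3, 3, 3)), 1)
  expect_equal(occupancy_fold_range(c(1, 10, 50)), 50)
  expect_equal(occupancy_fold_range(c(0, 10), pseudocount = 1), 10)
  expect_error(occupancy_fold_range(5), "at least 2")
  expect_error(occupancy_fold_range(c(0, 0)), "zero occupancy")
})

test_that("footprint classification is deterministic and scale-invariant", {
  prof <- data.frame(unit_index = 1:4,
                     occupancy = c(1, 1, 1, 1),
                     monomer_a_occ = c(1.0, 3.0, 1.0, 0.5),
                     monomer_b_occ = c(1.1, 1.0, 1.0, 1.2),
                     centroid_offset = c(0, -60, 80, 10))
  cl <- classify_dimers(prof)
  expect_equal(cl$orientation, c("centered", "upstream", "downstream",
                                 "centered"))
  expect_equal(cl$symmetry, c("symmetric", "asymmetric_a", "symmetric",
                              "asymmetric_b"))

  # multiplying the track by any c > 0 changes nothing
  prof_scaled <- prof
  for (col in c("occupancy", "monomer_a_occ", "monomer_b_occ"))
    prof_scaled[[col]] <- prof_scaled[[col]] * 17.3
  expect_equal(classify_dimers(prof_scaled)$symmetry, cl$symmetry)
  expect_equal(classify_dimers(prof_scaled)$orientation, cl$orientation)

  # mirror-imaging a profile flips upstream <-> downstream
  mirror <- prof; mirror$centroid_offset <- -prof$centroid_offset
  flipped <- classify_dimers(mirror)$orientation
  expect_equal(flipped[cl$orientation == "upstream"], "downstream")
  expect_equal(flipped[cl$orientation == "downstream"], "upstream")
})

test_that("symmetric vs one-monomer truth footprints are recovered", {
  # 10 units, alternating truth: odd units carry a symmetric dimer-spanning
  # footprint, even units a monomer-A nucleosomal footprint; ~50x coverage
  arr <- evolve_array(build_dimer(), 10, 0.05, seed = 2)
  arr$truth_occupancy <- rep(1, 10)
  arr$truth_fraction_weights <- matrix(0.25, 10, 4,
                                       dimnames = list(NULL, SALT_FRACTIONS))
  sym_model <- fragment_model(c(subnucleosomal = 0, nucleosomal = 0,
                                dimeric = 1), sds = c(1, 1, 5))
  asym_model <- fragment_model(c(subnucleosomal = 0, nucleosomal = 1,
                                 dimeric = 0), sds = c(1, 10, 1))
  truth <- rep(c("symmetric", "asymmetric_a"), 5)
  frags <- list()
  for (i in 1:10) {
    one <- arr
    one$truth_occupancy <- replace(rep(0, 10), i, 1)
    frags[[i]] <- simulate_fragments(
      one, if (truth[i] == "symmetric") sym_model else asym_model,
      60, seed = 100 + i, jitter_sd = 5,
      center = if (truth[i] == "symmetric") 170 else 85)
  }
  fr <- do.call(rbind, frags)
  hits <- data.frame(fragment_id = fr$fragment_id, ref_name = arr$name,
                     start = fr$start, end = fr$start + fr$length,
                     strand = "+", n_mismatches = 0L)
  track <- build_track(hits, array_sequence(arr))
  prof <- classify_dimers(per_dimer_occupancy(track, unit_intervals(arr),
                                              box_starts(arr)))
  expect_gte(mean(prof$symmetry == truth), 0.95)
})

test_that("pairwise identity equals the direct Hamming oracle", {
  u <- build_dimer()$sequence
  expect_equal(pairwise_identity(c(u, u))[1, 2], 100)
  v <- mutate_k(u, 34, seed = 3)
  m <- pairwise_identity(c(a = u, b = v))
  expect_equal(m["a", "b"], 90.0)          # 306/340
  expect_equal(diag(m), c(a = 100, b = 100))

  arr <- evolve_array(build_dimer(), 8, 0.08, seed = 4)
  got <- pairwise_identity(arr)
  seqs <- vapply(arr$units, `[[`, character(1), "sequence")
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(got[i, j],
                 100 * (1 - hamming_oracle(seqs[i], seqs[j]) / 340))
  }
  expect_error(pairwise_identity(c("ACGT", "ACG")), "equal length")
})
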