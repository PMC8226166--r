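test_that("schedule validation enforces exactness and noise margins", {
  ep <- data.frame(res_a = 3, res_b = 8, fraction = 0.5)
  expect_s3_class(association_schedule(ep, 100), "association_schedule")
  # fraction x frames must be an integer
  expect_error(association_schedule(data.frame(res_a = 3, res_b = 8,
                                               fraction = 0.19), 50),
               "integer")
  expect_error(association_schedule(data.frame(res_a = 3, res_b = 8,
                                               fraction = 1.2), 10),
               "fractions")
  # a 3.2 A contact with sigma = 0.4 could cross the 4 A boundary
  expect_error(association_schedule(ep, 100, noise_sigma = 0.4),
               "below the 4 A cutoff")
  ep_short <- data.frame(res_a = 3, res_b = 8, fraction = 0.5,
                         contact_distance = 1.0)
  expect_error(association_schedule(ep_short, 100, apart_distance = 6,
                                    noise_sigma = 0.9),
               "above the 4 A cutoff")
  expect_error(association_schedule(data.frame(res_a = c(3, 3),
                                               res_b = c(8, 8),
                                               fraction = c(0.5, 0.25)), 100),
               "distinct residue pairs")
})

test_that("identical seeds reproduce trajectories exactly, different seeds do not", {
  a <- h3_dimer_fixture("extended", n_frames = 100, seed = 9)
  b <- h3_dimer_fixture("extended", n_frames = 100, seed = 9)
  expect_identical(a$trajectory$xyz, b$trajectory$xyz)
  expect_identical(a$ground_truth$labels, b$ground_truth$labels)
  c <- h3_dimer_fixture("extended", n_frames = 100, seed = 10)
  expect_false(identical(a$trajectory$xyz, c$trajectory$xyz))
})

test_that("the analysis pipeline recovers scheduled persistence exactly", {
  fix <- h3_dimer_fixture("extended", n_frames = 100, seed = 3)
  cs <- contact_series(fix$trajectory, include_intra = FALSE)
  for (k in names(fix$ground_truth$fractions)) {
    expect_identical(persistence_fraction(cs, k),
                     unname(fix$ground_truth$fractions[k]))
  }
  map <- build_interaction_map(cs)
  expect_equal(count_intermolecular(map),
               fix$ground_truth$expected_intermolecular)
  # the star episode is the phospho-T3 / dimethyl-R8 salt bridge
  expect_identical(map$category[map$pair == "A:3-B:8"], "R_pT_saltbridge")
})

test_that("recovery is exact under sigma = 0.3 noise with wide separation margins", {
  spec <- builtin_peptides()$P1M2
  sched <- association_schedule(
    data.frame(res_a = 3, res_b = 8, fraction = 0.65,
               contact_distance = 3.0),
    n_frames = 40, apart_distance = 25, noise_sigma = 0.3, seed = 12)
  fix <- generate_dimer_trajectory(spec, spec, "extended", sched)
  cs <- contact_series(fix$trajectory, include_intra = FALSE)
  expect_identical(persistence_fraction(cs, "A:3-B:8"), 0.65)
  expect_equal(count_intermolecular(build_interaction_map(cs)), 1)
})

test_that("helical geometry supports scheduled association too", {
  spec <- builtin_peptides()$P1M2
  sched <- association_schedule(
    data.frame(res_a = c(3, 2), res_b = c(8, 9), fraction = c(0.8, 0.3)),
    n_frames = 20, seed = 4)
  fix <- generate_dimer_trajectory(spec, spec, "helical", sched)
  cs <- contact_series(fix$trajectory, include_intra = FALSE)
  expect_identical(persistence_fraction(cs, "A:3-B:8"), 0.8)
  expect_identical(persistence_fraction(cs, "A:2-B:9"), 0.3)
})

test_that("chains move rigidly: internal geometry is preserved up to the noise clip", {
  fix <- h3_dimer_fixture("extended", n_frames = 100, seed = 5)
  traj <- fix$trajectory
  iB <- which(traj$atoms$chain_id == "B")
  ref <- dist(traj$xyz[iB, , 1])
  # both compared frames are noisy: each pair distance sits within
  # 2 x (1.3 sigma) of the rigid ideal, so frame-to-frame shifts are
  # bounded by twice that
  bound <- 2 * (2 * 1.3 * 0.05)
  for (f in c(10, 50, 100)) {
    expect_lt(max(abs(dist(traj$xyz[iB, , f]) - ref)), bound + 1e-9)
  }
})

test_that("geometrically conflicting episodes are reported as infeasible", {
  spec <- builtin_peptides()$P1M2
  # one residue of A cannot touch both ends of B at once
  sched <- association_schedule(
    data.frame(res_a = c(1, 1), res_b = c(1, 12), fraction = c(0.5, 0.25)),
    n_frames = 20, seed = 6)
  expect_error(generate_dimer_trajectory(spec, spec, "extended", sched),
               "infeasible schedule.*episodes 1, 2")
  # episodes must reference residues inside the chains
  sched2 <- association_schedule(
    data.frame(res_a = 13, res_b = 1, fraction = 0.5), n_frames = 20)
  expect_error(generate_dimer_trajectory(spec, spec, "extended", sched2),
               "outside the chains")
})

test_that("an empty schedule produces a contact-free, burial-free dimer", {
  spec <- builtin_peptides()$P1M2
  sched <- association_schedule(
    data.frame(res_a = integer(0), res_b = integer(0), fraction = numeric(0)),
    n_frames = 10, seed = 2)
  fix <- generate_dimer_trajectory(spec, spec, "extended", sched)
  cs <- contact_series(fix$trajectory, include_intra = FALSE)
  expect_equal(mean_ncc(cs), 0)
  expect_equal(nrow(build_interaction_map(cs)), 0)
  expect_equal(fix$ground_truth$expected_intermolecular, 0)
})

test_that("fixtures serialize to PDB + topology + ground-truth JSON", {
  fix <- h3_dimer_fixture("extended", n_frames = 100, seed = 5)
  d <- withr::local_tempdir()
  paths <- write_fixture(fix, d, name = "fx", label = "P1M2/P1M2",
                         conformation = "extended")
  expect_true(all(file.exists(unlist(paths))))
  gt <- jsonlite::read_json(paths$ground_truth)
  expect_equal(gt$expected_intermolecular, 4)
  expect_equal(gt$fractions[["A:3-B:8"]], 0.98)
  topo <- read_topology(paths$topology)
  expect_identical(topo$conformation, "extended")
  expect_identical(compute_formal_charge(topo$chains$A), 3L)
})
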