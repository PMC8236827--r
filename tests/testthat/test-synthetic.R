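test_that("planted-column alignments are reproducible and well-formed", {
  spec <- list(group_sizes = c(g1 = 10, g2 = 10), length = 20,
               planted = data.frame(column = 5, g1 = "E", g2 = "Q"))
  m1 <- do.call(make_grouped_msa, c(spec, seed = 11))
  m2 <- do.call(make_grouped_msa, c(spec, seed = 11))
  expect_identical(m1$grouped$alignment$seqs, m2$grouped$alignment$seqs)
  m3 <- do.call(make_grouped_msa, c(spec, seed = 12))
  expect_false(identical(m1$grouped$alignment$seqs,
                         m3$grouped$alignment$seqs))
  # planted column is fully conserved within groups with the given letters
  mat <- alignment_matrix(m1$grouped$alignment)
  expect_true(all(mat[m1$grouped$groups$g1, 5] == "E"))
  expect_true(all(mat[m1$grouped$groups$g2, 5] == "Q"))
  # at full background conservation, MI is nonzero only at the plant
  mc <- make_grouped_msa(c(g1 = 10, g2 = 10), length = 20,
                         planted = data.frame(column = 5, g1 = "E",
                                              g2 = "Q"),
                         background_conservation = 1, seed = 2)
  mi <- mi_scores(mc$grouped)$score
  expect_gt(mi[5], 0)
  expect_equal(mi[-5], rep(0, 19))
  expect_error(make_grouped_msa(planted = data.frame(column = c(3, 3),
                                                     axl = "E",
                                                     tyro3_mer = "Q")),
               "conflicting")
})

test_that("planted columns rank first under noise in nearly all seeds", {
  # Multi-RELIEF tolerates fully uniform background noise; mutual
  # information is scored at the generator's realistic conservation
  # default, because a high-entropy random column with group-disjoint
  # letter supports ties any separating column at the group-entropy
  # bound log(2) (small-sample MI saturation).
  hits_mi <- 0; hits_rl <- 0
  for (s in 1:100) {
    noisy <- make_grouped_msa(c(g1 = 6, g2 = 6), length = 20,
                              planted = data.frame(column = 11, g1 = "E",
                                                   g2 = "Q"),
                              background_conservation = 0, seed = s)
    if (rank_and_select(multirelief_scores(noisy$grouped, seed = s),
                        top_k = 1) == 11)
      hits_rl <- hits_rl + 1
    cons <- make_grouped_msa(c(g1 = 6, g2 = 6), length = 20,
                             planted = data.frame(column = 11, g1 = "E",
                                                  g2 = "Q"),
                             seed = s)
    if (rank_and_select(mi_scores(cons$grouped), top_k = 1) == 11)
      hits_mi <- hits_mi + 1
  }
  expect_gte(hits_mi, 95)
  expect_gte(hits_rl, 95)
})

test_that("toy interfaces place exactly the planted geometry", {
  toy <- make_toy_interface(c(3, 3), list(
    list(type = "saltbridge", distance = 3.5),
    list(type = "hydrophobic", distance = 4.0)))
  got <- detect_contacts(toy$frame, "all",
                         params = contact_params(hbond_mode =
                                                   "donor-acceptor"))
  expect_equal(sort(got$key), sort(toy$truth$key))
  expect_equal(got$distance[match(toy$truth$key, got$key)],
               toy$truth$distance, tolerance = 1e-9)
  # structures survive a PDB round trip
  pdb <- tempfile(fileext = ".pdb")
  write_frames(toy$frame, pdb)
  back <- get_frame(read_frames(pdb, toy$frame$sides), 1)
  expect_equal(detect_contacts(back, "all",
                               contact_params(hbond_mode =
                                                "donor-acceptor"))$key,
               got$key)
  expect_error(make_toy_interface(c(1, 1), list(
    list(type = "saltbridge", distance = 3.5),
    list(type = "saltbridge", distance = 3.5))),
    "n_per_side")
  # cramming planted rows together is an infeasible packing
  expect_error(make_toy_interface(c(2, 2), list(
    list(type = "saltbridge", distance = 3.5),
    list(type = "saltbridge", distance = 3.5)), spacing = 2),
    "infeasible packing")
})

test_that("ensembles honour their occupancy plan and jitter margins", {
  ens <- make_ensemble(data.frame(type = "saltbridge", on = 3.5,
                                  off = 6.0),
                       occupancy = matrix(c(80, 35, 55, 70), nrow = 1),
                       n_frames = 40, n_replicas = 4, seed = 21)
  oc <- occupancy(ens$framesets, "saltbridge")
  expect_equal(unname(oc[1, ]),
               ens$truth$realized[order(ens$truth$replica)],
               tolerance = 1e-9)
  # the consistent/stable pattern mirrors a stable salt bridge
  expect_true(classify_stability(oc)$consistent[[1]])
  # determinism per seed
  ens2 <- make_ensemble(data.frame(type = "saltbridge", on = 3.5,
                                   off = 6.0),
                        occupancy = matrix(c(80, 35, 55, 70), nrow = 1),
                        n_frames = 40, n_replicas = 4, seed = 21)
  expect_identical(ens$framesets$replica2$xyz, ens2$framesets$replica2$xyz)
  # invalid geometry orders and oversized jitter are rejected
  expect_error(make_ensemble(data.frame(type = "saltbridge", on = 4.5,
                                        off = 6.0), 50, 10, 1),
               "on < cutoff < off")
  expect_error(make_ensemble(data.frame(type = "saltbridge", on = 3.95,
                                        off = 6.0), 50, 10, 1,
                             jitter_sd = 0.05),
               "jitter")
})

test_that("energy tables carry their planted outliers and reproduce", {
  et <- make_energy_table(n = 30, outliers = data.frame(resno = 7,
                                                        e_elec = -200),
                          seed = 5)
  expect_equal(et$truth, 7)
  expect_equal(et$table$e_elec[7], -200)
  expect_equal(et$table$e_total, et$table$e_vdw + et$table$e_elec)
  et2 <- make_energy_table(n = 30, outliers = data.frame(resno = 7,
                                                         e_elec = -200),
                           seed = 5)
  expect_identical(et$table, et2$table)
  expect_error(make_energy_table(n = 10,
                                 outliers = data.frame(resno = 11,
                                                       e_elec = 0)),
               "out of range")
})
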