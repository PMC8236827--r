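test_that("column profiles count symbols per group and marginalise", {
  g <- tiny_grouped()
  pr <- column_profile(g, 4)  # E,E | Q,Q
  expect_equal(unname(pr$f_a[c("E", "Q")]), c(0.5, 0.5))
  expect_equal(unname(pr$f_ai["E", "g1"]), 1.0)
  expect_equal(sum(pr$f_a), 1, tolerance = 1e-9)
  expect_equal(colSums(pr$f_ai), c(g1 = 1, g2 = 1), tolerance = 1e-9)
  # group-weighted marginal re-sums to f_a, also on random columns
  set.seed(11)
  for (k in 1:20) {
    gr <- random_grouped(n_groups = sample(2:3, 1), L = 6)
    prk <- column_profile(gr, sample(6, 1),
                          pseudocount = sample(c(0, 0.5), 1))
    expect_equal(as.vector(prk$f_ai %*% prk$f_i), unname(prk$f_a),
                 tolerance = 1e-9)
  }
  # all-gap column is a single-symbol profile on the gap
  ag <- assign_groups(as_alignment(c("x", "y"), c("-A", "-C")),
                      list(g1 = "x", g2 = "y"))
  expect_equal(unname(column_profile(ag, 1)$f_a["-"]), 1)
  expect_error(column_profile(g, 9), "out of range")
})

test_that("mutual information has its fixed points and closed forms", {
  g <- tiny_grouped()
  # identical column in all sequences
  expect_equal(mutual_information(column_profile(g, 1)), 0)
  # fully separating equal-size groups: log 2 nats
  expect_equal(mutual_information(column_profile(g, 4)), log(2),
               tolerance = 1e-12)
  # identical distribution in both groups (mixed but group-independent)
  gm <- assign_groups(as_alignment(paste0("s", 1:4),
                                   c("E", "Q", "E", "Q")),
                      list(g1 = c("s1", "s2"), g2 = c("s3", "s4")))
  expect_equal(mutual_information(column_profile(gm, 1)), 0,
               tolerance = 1e-12)
})

test_that("MI agrees with the brute-force double sum and its bounds", {
  set.seed(42)
  worst <- 0
  for (k in 1:1000) {
    gr <- random_grouped(n_groups = sample(2:3, 1),
                         n_per_group = sample(2:5, 1), L = 4)
    pr <- column_profile(gr, sample(4, 1))
    mi <- mutual_information(pr)
    expect_equal(mi, mi_bruteforce(pr), tolerance = 1e-12)
    expect_gte(mi, 0)
    expect_lte(mi, sum(pr$f_i * log(1 / pr$f_i)) + 1e-12)
    worst <- max(worst, abs(mi - mi_bruteforce(pr)))
  }
  expect_lt(worst, 1e-12)
})

test_that("MI is invariant under amino-acid relabelling", {
  set.seed(7)
  for (k in 1:25) {
    gr <- random_grouped(L = 5)
    perm <- setNames(sample(c("F", "G", "H", "I")), c("A", "C", "D", "E"))
    relabel <- vapply(gr$alignment$seqs, function(s)
      paste(perm[strsplit(s, "")[[1]]], collapse = ""), "")
    gr2 <- assign_groups(as_alignment(gr$alignment$ids, relabel),
                         lapply(gr$groups, identity))
    p <- sample(5, 1)
    expect_equal(mutual_information(column_profile(gr, p)),
                 mutual_information(column_profile(gr2, p)),
                 tolerance = 1e-12)
  }
})

test_that("permutation null flags planted columns and respects alpha", {
  msa <- make_grouped_msa(c(g1 = 6, g2 = 6), length = 51,
                          planted = data.frame(column = 26, g1 = "E",
                                               g2 = "Q"),
                          background_conservation = 0.85, seed = 3)
  st <- mi_sdp_call(msa$grouped, permutations = 200, seed = 9)
  expect_true(st$flag[26])
  expect_equal(attr(st, "null_summary")$seed, 9)
  # no group signal -> no flags
  g0 <- assign_groups(as_alignment(paste0("s", 1:4), rep("AAAA", 4)),
                      list(g1 = c("s1", "s2"), g2 = c("s3", "s4")))
  expect_false(any(mi_sdp_call(g0, permutations = 20, seed = 1)$flag))
  # degenerate level flags everything
  expect_true(all(mi_sdp_call(g0, permutations = 20, alpha = 1,
                              seed = 1)$flag))
  expect_error(mi_sdp_call(g0, permutations = 0), "permutations")
})

test_that("Multi-RELIEF reproduces the hand-traced update and its bound", {
  g <- tiny_grouped()
  rs <- multi_relief(g, seed = 1)
  # constant columns stay at 0; fully separating columns reach 1
  expect_equal(unname(rs$w[1:3]), c(0, 0, 0))
  expect_equal(unname(rs$w[4:5]), c(1, 1))
  expect_equal(rs$m, 4)
  # printed-sign convention flips the result
  rs2 <- multi_relief(g, seed = 1, sign_convention = "as_printed")
  expect_equal(unname(rs2$w[4:5]), c(-1, -1))
  # |w| <= 1 on random alignments
  set.seed(5)
  for (k in 1:200) {
    gr <- random_grouped(n_per_group = sample(2:4, 1), L = 8)
    expect_lte(max(abs(multi_relief(gr, seed = k)$w)), 1)
  }
  # a single-sequence group has no hit
  g1 <- assign_groups(as_alignment(paste0("s", 1:3), rep("ACDE", 3)),
                      list(a = "s1", b = c("s2", "s3")))
  expect_error(multi_relief(g1), "degenerate group")
})

test_that("each-once Multi-RELIEF is record-order invariant without ties", {
  # distances are unique by construction (no tie-breaking randomness)
  aln <- as_alignment(c("a1", "a2", "a3", "b1", "b2", "b3"),
                      c("AAAAEE", "AAACEE", "ACCCEE",
                        "DDDDQQ", "DDDCQQ", "DCCCQQ"))
  gs <- list(g1 = c("a1", "a2", "a3"), g2 = c("b1", "b2", "b3"))
  g <- assign_groups(aln, gs)
  w1 <- multi_relief(g, seed = 1)$w
  ord <- c(4, 2, 6, 1, 3, 5)
  g2 <- assign_groups(as_alignment(aln$ids[ord], aln$seqs[ord]), gs)
  w2 <- multi_relief(g2, seed = 99)$w
  expect_equal(w1, w2)
})

test_that("sequence harmony matches hand-evaluated divergences", {
  g <- tiny_grouped()
  expect_equal(sequence_harmony(column_profile(g, 1)), 1)  # identical
  expect_equal(sequence_harmony(column_profile(g, 4)), 0)  # disjoint
  # pA = (0.5 E, 0.5 Q), pB = (1.0 E): literal hand evaluation
  gm <- assign_groups(as_alignment(paste0("s", 1:4),
                                   c("E", "Q", "E", "E")),
                      list(g1 = c("s1", "s2"), g2 = c("s3", "s4")))
  hand <- 1 - ((0.5 * log2(2 * 0.5 / 1.5) + 0.5 * log2(2 * 0.5 / 0.5)) +
                 (1.0 * log2(2 * 1.0 / 1.5))) / 2
  expect_equal(sequence_harmony(column_profile(gm, 1)), hand,
               tolerance = 1e-12)
  g3 <- random_grouped(n_groups = 3)
  expect_error(sequence_harmony(column_profile(g3, 1)), "2 groups")
})

test_that("separating columns outrank group-independent columns", {
  set.seed(21)
  for (k in 1:20) {
    msa <- make_grouped_msa(c(g1 = 5, g2 = 5), length = 12,
                            planted = data.frame(column = 6, g1 = "E",
                                                 g2 = "Q"),
                            background_conservation = 1, seed = k)
    mi <- mi_scores(msa$grouped)
    hm <- harmony_scores(msa$grouped)
    expect_equal(rank_and_select(mi, top_k = 1), 6)
    expect_equal(rank_and_select(hm, top_k = 1), 6)
    expect_true(all(mi$score[6] > mi$score[-6]))
    expect_true(all(hm$score[6] < hm$score[-6]))
  }
})

test_that("ranking is stable, tie-broken by column, direction-aware", {
  st <- sdpmapper:::new_score_table(c(0.9, 0.9, 0.1), method = "mi")
  expect_equal(rank_and_select(st, top_k = 2), c(1, 2))
  expect_equal(rank_and_select(st, top_k = 0), integer(0))
  expect_warning(all3 <- rank_and_select(st, top_k = 5), "clamped")
  expect_equal(all3, c(1, 2, 3))
  hm <- sdpmapper:::new_score_table(c(0.0, 1.0), method = "harmony")
  expect_equal(rank_and_select(hm, top_k = 1), 1)
  expect_equal(rank_and_select(st, threshold = 0.5), c(1, 2))
})
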