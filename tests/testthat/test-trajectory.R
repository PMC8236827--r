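test_that("occupancy counts frames after equilibration trimming", {
  ens <- make_ensemble(data.frame(type = "saltbridge", on = 3.5, off = 6.0),
                       occupancy = 100, n_frames = 10, n_replicas = 1,
                       seed = 2)
  oc <- occupancy(ens$framesets, "saltbridge")
  expect_equal(unname(oc[1, 1]), 100)
  expect_equal(unname(attr(oc, "frames_analyzed")), 10)
  # trimming removes frames from the denominator
  oc2 <- occupancy(ens$framesets, "saltbridge", equilibration = 4)
  expect_equal(unname(attr(oc2, "frames_analyzed")), 6)
  expect_error(occupancy(ens$framesets, "saltbridge", equilibration = 10),
               "no frames left")
  # watch-listed but never-seen keys appear as 0
  oc3 <- occupancy(ens$framesets, "saltbridge",
                   watch_keys = "saltbridge:A:99-B:99")
  expect_equal(unname(oc3["saltbridge:A:99-B:99", 1]), 0)
})

test_that("occupancy is invariant to frame order within a replica", {
  ens <- make_ensemble(data.frame(type = "saltbridge", on = 3.5, off = 6.0),
                       occupancy = 50, n_frames = 30, n_replicas = 1,
                       seed = 6)
  fs <- ens$framesets[[1]]
  perm <- sample(n_frames(fs))
  shuffled <- fs; shuffled$xyz <- fs$xyz[perm, ]
  expect_equal(unclass(occupancy(list(r1 = fs), "saltbridge")),
               unclass(occupancy(list(r1 = shuffled), "saltbridge")))
})

test_that("occupancy estimates recover prescribed rates at 350 frames", {
  targets <- c(10, 25, 26, 50, 90)
  ens <- make_ensemble(data.frame(type = rep("saltbridge", 5),
                                  on = 3.5, off = 6.0),
                       occupancy = targets, n_frames = 350,
                       n_replicas = 1, seed = 8)
  oc <- occupancy(ens$framesets, "saltbridge")
  se <- sqrt(targets * (100 - targets) / 350)
  expect_true(all(abs(oc[, 1] - targets) <= 3 * se))
  # measured occupancies equal the generator's realized truth exactly
  truth <- ens$truth$realized[match(rownames(oc), ens$truth$key)]
  expect_equal(unname(oc[, 1]), truth, tolerance = 1e-9)
  # the 25%-target contact is called unstable exactly when estimate <= 25
  sc <- classify_stability(oc, threshold = 25)
  expect_equal(unname(sc$stable[, 1]), unname(oc[, 1] > 25))
})

test_that("stability calls use a strict 25% threshold and all replicas", {
  m <- matrix(c(81.14, 34.57, 55.41, 70.57,
                NA, NA, NA, 25.14,
                26, 25, 30, 40), nrow = 3, byrow = TRUE,
              dimnames = list(c("saltbridge:A:70-B:414",
                                "saltbridge:A:56-B:308",
                                "saltbridge:A:1-B:1"),
                              paste0("r", 1:4)))
  oc <- new_occupancy_table(m)
  sc <- classify_stability(oc)
  expect_true(sc$consistent[["saltbridge:A:70-B:414"]])
  # 25.14 is stable in its replica (strict >25) but not consistent
  expect_equal(unname(sc$stable["saltbridge:A:56-B:308", ]),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_false(sc$consistent[["saltbridge:A:56-B:308"]])
  # a cell exactly at 25 is unstable
  expect_false(sc$stable["saltbridge:A:1-B:1", 2])
  expect_false(sc$consistent[["saltbridge:A:1-B:1"]])
  # any-replica consistency mode
  expect_true(classify_stability(oc, require_all = FALSE)$consistent[[2]])
  # receptor residues parsed from canonical keys
  expect_equal(attr(oc, "meta")$receptor_res, c(70, 56, 1))
})

test_that("RMSD to the average structure behaves under rigid motion", {
  toy <- make_toy_interface(c(2, 2),
                            list(list(type = "saltbridge", distance = 3.5)))
  f <- toy$frame
  # identical frames -> zero everywhere
  fs <- as_frameset(list(f, f, f))
  expect_equal(rmsd_to_average(fs), rep(0, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
  # a rigidly translated copy superposes to zero
  ft <- f; ft$atoms$x <- ft$atoms$x + 5; ft$atoms$y <- ft$atoms$y - 2
  expect_equal(rmsd_to_average(as_frameset(list(f, ft))), rep(0, 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  # hand formula on a fit-proof toy: a square of 4 atoms whose second
  # frame adds an alternating z-pattern (+1,-1,+1,-1). The pattern is
  # orthogonal to every rigid-body mode, so superposition removes
  # nothing; each frame then sits sqrt(sum(d^2)/N) = 0.5 A from the
  # average (d = 0.5 A on every atom).
  sq <- sdp_frame(data.frame(chain = c("A", "A", "B", "B"),
                             resno = c(1, 2, 1, 2), ins = "",
                             resid = "GLY", elety = "CA", element = "C",
                             x = c(1, -1, -1, 1), y = c(1, 1, -1, -1),
                             z = 0),
                  c(A = "receptor", B = "ligand"))
  sq2 <- sq; sq2$atoms$z <- c(1, -1, 1, -1)
  r <- rmsd_to_average(as_frameset(list(sq, sq2)))
  expect_equal(r, c(0.5, 0.5), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(attr(rmsd_to_average(fs, units = "nm"), "units")),
               "nm")
  expect_error(rmsd_to_average(fs, selection = integer(0)), "empty")
})

test_that("radius of gyration matches its direct-sum definition", {
  single <- sdp_frame(data.frame(chain = c("A", "B"), resno = 1, ins = "",
                                 resid = "GLY", elety = "CA", element = "C",
                                 x = c(0, 30), y = 0, z = 0),
                      c(A = "receptor", B = "ligand"))
  one <- frame_side(single, "receptor")
  expect_equal(radius_of_gyration(one), 0)
  # two unit-mass atoms 2 A apart -> 1 A
  two <- sdp_frame(data.frame(chain = c("A", "B"), resno = 1, ins = "",
                              resid = "GLY", elety = "CA", element = "C",
                              x = c(0, 2), y = 0, z = 0),
                   c(A = "receptor", B = "ligand"))
  expect_equal(radius_of_gyration(two, mass_weighted = FALSE), 1)
  # random 100-atom frame vs the pairwise-distance identity:
  # Rg^2 = sum_ij m_i m_j d_ij^2 / (2 M^2)
  set.seed(17)
  els <- sample(c("C", "N", "O", "S", "H"), 100, replace = TRUE)
  fr <- sdp_frame(data.frame(chain = rep(c("A", "B"), 50), resno = 1,
                             ins = "", resid = "GLY", elety = "X",
                             element = els, x = stats::rnorm(100),
                             y = stats::rnorm(100), z = stats::rnorm(100)),
                  c(A = "receptor", B = "ligand"))
  m <- sdpmapper:::atomic_masses()[els]
  d2 <- as.matrix(stats::dist(fr$atoms[, c("x", "y", "z")]))^2
  oracle <- sqrt(sum(outer(m, m) * d2) / (2 * sum(m)^2))
  expect_equal(radius_of_gyration(fr), unname(oracle), tolerance = 1e-10)
})

test_that("count distributions get quartiles, 2xIQR whiskers, outliers, r", {
  const <- rep(4, 10)
  ds <- distribution_summary(const)
  expect_equal(unname(ds$A$iqr), 0)
  expect_length(ds$A$outliers, 0)
  # a series paired with itself correlates perfectly
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  expect_equal(distribution_summary(x, x)$r, 1)
  # planted heavy tail beyond Q3 + 2 IQR is flagged
  y <- c(rep(c(4, 5, 6), 10), 40)
  dy <- distribution_summary(y)
  expect_equal(unname(dy$A$whiskers["upper"]),
               unname(stats::quantile(y, 0.75) +
                        2 * (stats::quantile(y, 0.75) -
                               stats::quantile(y, 0.25))))
  expect_equal(dy$A$outliers, 40)
  # unequal lengths fall back to quantile-profile correlation
  dq <- distribution_summary(x, c(x, 9))
  expect_equal(dq$r_method, "pearson_quantile_profiles")
  expect_error(distribution_summary(c(1, 2, 3)), "at least 4")
})
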