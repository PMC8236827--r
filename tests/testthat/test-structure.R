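test_that("frame ensembles read from multi-model files and directories", {
  toy <- make_toy_interface(c(2, 2),
                            list(list(type = "saltbridge", distance = 3.5)))
  f2 <- toy$frame; f2$atoms$x <- f2$atoms$x + 1
  f3 <- toy$frame; f3$atoms$z <- f3$atoms$z + 2
  fs <- as_frameset(list(toy$frame, f2, f3))
  pdb <- tempfile(fileext = ".pdb")
  write_frames(fs, pdb)
  back <- read_frames(pdb, c(A = "receptor", B = "ligand"))
  expect_equal(n_frames(back), 3)
  expect_equal(get_frame(back, 2)$atoms$x, f2$atoms$x, tolerance = 1e-3)

  # directory of single-model files, lexicographic order
  dd <- tempfile(); dir.create(dd)
  write_frames(toy$frame, file.path(dd, "f_01.pdb"))
  write_frames(f2, file.path(dd, "f_02.pdb"))
  back2 <- read_frames(dd, c(A = "receptor", B = "ligand"))
  expect_equal(n_frames(back2), 2)
  expect_equal(get_frame(back2, 2)$atoms$x, f2$atoms$x, tolerance = 1e-3)

  # topology error: frame 2 missing one atom
  f2drop <- f2; f2drop$atoms <- f2drop$atoms[-1, ]
  write_frames(f2drop, file.path(dd, "f_02.pdb"))
  expect_error(read_frames(dd, c(A = "receptor", B = "ligand")),
               "topology")
  # side-spec completeness
  expect_error(read_frames(pdb, c(A = "receptor")), "absent from side")
  expect_error(read_frames(tempfile(), c(A = "receptor")), "no such")
})

test_that("SASA matches analytic spheres and dense quadrature", {
  lone <- sdp_frame(data.frame(chain = c("A", "B"), resno = 1, ins = "",
                               resid = "GLY", elety = "CA", element = "C",
                               x = c(0, 50), y = 0, z = 0),
                    c(A = "receptor", B = "ligand"))
  s <- sasa(lone)
  expect_equal(s$atom$sasa, rep(4 * pi * 3.1^2, 2), tolerance = 0.01)
  expect_equal(s$radii_set, "bondi")
  expect_equal(s$residue$sasa, s$atom$sasa)

  # atom fully enclosed by a tight shell of neighbours -> 0
  pts <- sdpmapper:::sphere_points(40) * 1.2
  shell <- data.frame(chain = "A", resno = seq_len(41), ins = "",
                      resid = "GLY", elety = "CA", element = "C",
                      x = c(0, pts[, 1]), y = c(0, pts[, 2]),
                      z = c(0, pts[, 3]))
  shell <- rbind(shell, data.frame(chain = "B", resno = 42, ins = "",
                                   resid = "GLY", elety = "CA",
                                   element = "C", x = 50, y = 0, z = 0))
  sh <- sasa(sdp_frame(shell, c(A = "receptor", B = "ligand")))
  expect_equal(sh$atom$sasa[1], 0)

  # 960-point quadrature within 2% of a 10,000-point oracle per residue
  set.seed(13)
  for (k in 1:3) {
    n <- 50
    cl <- data.frame(chain = "A", resno = rep(1:10, each = 5), ins = "",
                     resid = "GLY", elety = paste0("C", rep(1:5, 10)),
                     element = "C",
                     x = stats::rnorm(n, sd = 4), y = stats::rnorm(n, sd = 4),
                     z = stats::rnorm(n, sd = 4))
    cl2 <- cl; cl2$chain <- "B"; cl2$x <- cl2$x + 60; cl2$resno <- cl2$resno + 10
    fr <- sdp_frame(rbind(cl, cl2), c(A = "receptor", B = "ligand"))
    fast <- sasa(fr, points = 960)$residue
    slow <- sasa(fr, points = 10000)$residue
    denom <- pmax(slow$sasa, 1)
    expect_lt(max(abs(fast$sasa - slow$sasa) / denom), 0.02)
  }

  # fully coincident spheres: consistent exposure, total about one sphere
  co <- sdp_frame(data.frame(chain = c("A", "B"), resno = 1, ins = "",
                             resid = "GLY", elety = "CA", element = "C",
                             x = 0, y = 0, z = 0),
                  c(A = "receptor", B = "ligand"))
  tot <- sum(sasa(co, points = 960)$atom$sasa)
  oracle <- sum(sasa(co, points = 100000)$atom$sasa)
  one_sphere <- 4 * pi * 3.1^2
  expect_lt(abs(tot - oracle), 0.15 * one_sphere)

  expect_error(sasa(sdp_frame(data.frame(chain = c("A", "B"), resno = 1,
                                         ins = "", resid = "UNK",
                                         elety = "Q1", element = "Q",
                                         x = c(0, 9), y = 0, z = 0),
                              c(A = "receptor", B = "ligand"))),
               "unknown element")
})

test_that("interface classification separates core, rim and non-interface", {
  # ligand residue 1 sandwiched inside a receptor cage -> core;
  # ligand residue 2 touching the receptor edge -> rim;
  # ligand residue 3 far away -> non-interface.
  cage <- sdpmapper:::sphere_points(60) * 4.0
  atoms <- rbind(
    data.frame(chain = "A", resno = seq_len(60), ins = "", resid = "GLY",
               elety = "CA", element = "C", x = cage[, 1], y = cage[, 2],
               z = cage[, 3]),
    data.frame(chain = "A", resno = 61, ins = "", resid = "GLY",
               elety = "CA", element = "C", x = 20, y = 0, z = 0),
    data.frame(chain = "B", resno = c(1, 2, 3), ins = "", resid = "GLY",
               elety = "CA", element = "C", x = c(0, 20 + 3.5, 60),
               y = 0, z = 0))
  fr <- sdp_frame(atoms, c(A = "receptor", B = "ligand"))
  cl <- classify_interface(fr)
  b <- as.data.frame(cl)
  lig <- b[b$side == "ligand", ]
  expect_equal(lig$region[lig$resno == 1], "core")
  expect_gte(lig$burial_fraction[lig$resno == 1], 0.95)
  expect_equal(lig$region[lig$resno == 2], "rim")
  expect_equal(lig$region[lig$resno == 3], "non-interface")
  expect_equal(lig$dsasa[lig$resno == 3], 0, tolerance = 1e-9)
  expect_gt(attr(cl, "bsa"), 0)
})

test_that("buried surface area decays to zero as the sides separate", {
  base <- make_toy_interface(c(2, 2),
                             list(list(type = "saltbridge",
                                       distance = 3.5)))$frame
  bsa <- vapply(c(0, 2, 6, 20), function(dx) {
    fr <- base
    lig <- fr$atoms$chain == "B"
    fr$atoms$x[lig] <- fr$atoms$x[lig] + dx
    attr(classify_interface(fr), "bsa")
  }, numeric(1))
  expect_true(all(diff(bsa) <= 1e-6))
  expect_gt(bsa[1], 0)
  expect_equal(bsa[4], 0, tolerance = 1e-9)
})
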