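#' Generate a grouped alignment with planted group-separating columns
#'
#' Background columns are group-independent: each draws a consensus
#' letter, kept per sequence with probability `background_conservation`
#' and replaced by a uniform draw from the alphabet otherwise. Planted
#' columns carry the specified per-group letters at within-group
#' conservation 1. Fully reproducible per seed. The defaults mirror the
#' study design the scorers target: a small receptor subfamily (5
#' mammalian orthologs) against its two sister paralogs pooled (10
#' sequences) over an immunoglobulin-like domain of ~100 columns.
#'
#' @param group_sizes Named integer vector of sequences per group
#'   (default `c(axl = 5, tyro3_mer = 10)`).
#' @param length Alignment columns (default 100).
#' @param planted data.frame with column `column` plus one letter column
#'   per group (named like `group_sizes`); duplicate planted columns are
#'   an error.
#' @param background_conservation Probability a background column's
#'   consensus letter is kept per sequence (default 0.85).
#' @param alphabet Symbols for background draws (default the 20 amino
#'   acids).
#' @param seed Integer seed.
#' @return List with `grouped` (an `sdp_grouped`) and `truth` (the
#'   planted data.frame plus `seed`).
#' @export
make_grouped_msa <- function(group_sizes = c(axl = 5, tyro3_mer = 10),
                             length = 100, planted = NULL,
                             background_conservation = 0.85,
                             alphabet = setdiff(aa_alphabet(), c("X", "-")),
                             seed = 1) {
  stopifnot(length >= 1L, background_conservation >= 0,
            background_conservation <= 1, all(group_sizes >= 1L))
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("group", seq_along(group_sizes))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot("column" %in% names(planted),
              all(names(group_sizes) %in% names(planted)))
    if (anyDuplicated(planted$column))
      stop("conflicting plants: column(s) planted twice: ",
           paste(unique(planted$column[duplicated(planted$column)]),
                 collapse = ", "))
    if (any(planted$column < 1L | planted$column > length))
      stop("planted column out of range")
  }
  n <- sum(group_sizes)
  grp <- rep(names(group_sizes), group_sizes)
  withr_seed(seed, {
    m <- matrix("", nrow = n, ncol = length)
    for (p in seq_len(length)) {
      cons <- sample(alphabet, 1L)
      keep <- stats::runif(n) < background_conservation
      m[, p] <- ifelse(keep, cons, sample(alphabet, n, replace = TRUE))
    }
    if (!is.null(planted)) {
      for (k in seq_len(nrow(planted))) {
        p <- planted$column[k]
        for (g in names(group_sizes))
          m[grp == g, p] <- planted[[g]][k]
      }
    }
    ids <- unlist(lapply(names(group_sizes), function(g)
      paste0(g, "_", seq_len(group_sizes[[g]]))))
    aln <- as_alignment(ids, apply(m, 1, paste, collapse = ""))
    grouped <- assign_groups(aln, split(ids, rep(names(group_sizes),
                                                 group_sizes)))
    list(grouped = grouped,
         truth = list(planted = planted, seed = seed,
                      background_conservation = background_conservation))
  })
}

toy_residue <- function(chain, resno, resid, atoms) {
  data.frame(chain = chain, resno = resno, ins = "", resid = resid,
             elety = names(atoms),
             element = vapply(atoms, `[[`, "", "element"),
             x = vapply(atoms, function(a) a$xyz[1], numeric(1)),
             y = vapply(atoms, function(a) a$xyz[2], numeric(1)),
             z = vapply(atoms, function(a) a$xyz[3], numeric(1)),
             stringsAsFactors = FALSE)
}

at <- function(element, x, y, z) list(element = element, xyz = c(x, y, z))

#' Build a two-chain toy interface with planted contacts
#'
#' Places chemically minimal residues (only the atoms the detectors need)
#' on two chains facing each other across the x = 0 plane, one planted
#' contact per row along y, with the prescribed geometry; filler glycines
#' sit far from the interface so no unplanned cross-side contact exists
#' (verified after construction; violation is an infeasible-packing
#' error).
#'
#' Planted contact specs (list entries):
#' * `list(type = "saltbridge", distance = )` - Glu OE1 (receptor) to
#'   Lys NZ (ligand) at `distance`.
#' * `list(type = "hbond", h_a_distance = , angle = )` - Ser OG-HG donor
#'   (receptor) to backbone O acceptor (ligand Gly), hydrogen-acceptor
#'   distance and D-H-A angle as given.
#' * `list(type = "hydrophobic", distance = )` - Ala CB to Ala CB.
#'
#' @param n_per_side Residues per chain, `c(receptor, ligand)`; must be
#'   at least the planted count.
#' @param planted List of contact specs (possibly empty).
#' @param spacing Row spacing along y in Angstrom (default 12, safely
#'   beyond every cutoff).
#' @param chains Chain ids, receptor first (default `c("A", "B")`).
#' @return List with `frame` (an `sdp_frame`) and `truth` (data.frame of
#'   planted keys, types and geometry).
#' @export
make_toy_interface <- function(n_per_side = c(4, 4), planted = list(),
                               spacing = 12, chains = c("A", "B")) {
  n_per_side <- rep_len(n_per_side, 2L)
  k <- length(planted)
  if (any(n_per_side < k))
    stop("n_per_side smaller than the planted contact count")
  recs <- list()
  truth <- NULL
  for (i in seq_len(k)) {
    pc <- planted[[i]]
    y <- (i - 1) * spacing
    if (pc$type == "saltbridge") {
      d <- pc$distance
      recs[[length(recs) + 1L]] <- toy_residue(chains[1], i, "GLU", list(
        CA = at("C", -d / 2 - 1.5, y, 0), OE1 = at("O", -d / 2, y, 0)))
      recs[[length(recs) + 1L]] <- toy_residue(chains[2], i, "LYS", list(
        NZ = at("N", d / 2, y, 0), CA = at("C", d / 2 + 1.5, y, 0)))
      geom <- c(distance = d, angle = NA)
    } else if (pc$type == "hydrophobic") {
      d <- pc$distance
      recs[[length(recs) + 1L]] <- toy_residue(chains[1], i, "ALA", list(
        CA = at("C", -d / 2 - 1.5, y, 0), CB = at("C", -d / 2, y, 0)))
      recs[[length(recs) + 1L]] <- toy_residue(chains[2], i, "ALA", list(
        CB = at("C", d / 2, y, 0), CA = at("C", d / 2 + 1.5, y, 0)))
      geom <- c(distance = d, angle = NA)
    } else if (pc$type == "hbond") {
      d <- pc$h_a_distance
      th <- pc$angle * pi / 180
      acc_x <- 1.1
      h <- c(acc_x - d, y, 0)
      og <- h + 0.96 * c(cos(th), sin(th), 0)
      recs[[length(recs) + 1L]] <- toy_residue(chains[1], i, "SER", list(
        CA = at("C", og[1] - 1.5, og[2] + 1.2, 0),
        OG = at("O", og[1], og[2], og[3]),
        HG = at("H", h[1], h[2], h[3])))
      recs[[length(recs) + 1L]] <- toy_residue(chains[2], i, "GLY", list(
        O = at("O", acc_x, y, 0), CA = at("C", acc_x + 1.5, y, 0)))
      geom <- c(distance = d, angle = pc$angle)
    } else stop("unknown planted contact type: ", pc$type)
    truth <- rbind(truth, data.frame(
      type = pc$type,
      key = sprintf("%s:%s:%d-%s:%d", pc$type, chains[1], i, chains[2], i),
      distance = geom["distance"], angle = geom["angle"],
      ligand_shift_axis = "x", stringsAsFactors = FALSE))
  }
  # far-field filler residues complete each chain
  for (s in 1:2) {
    extra <- n_per_side[s] - k
    if (extra > 0L) {
      for (j in seq_len(extra)) {
        y <- (k + j - 1) * spacing
        x0 <- if (s == 1) -9 else 9
        recs[[length(recs) + 1L]] <- toy_residue(chains[s], k + j, "GLY",
                                                 list(CA = at("C", x0, y, 0)))
      }
    }
  }
  atoms <- do.call(rbind, recs)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$o <- 1
  sides <- stats::setNames(c("receptor", "ligand"), chains)
  frame <- sdp_frame(atoms, sides)
  check_packing(frame, truth)
  rownames(truth) <- NULL
  list(frame = frame, truth = truth)
}

# no cross-side atom pair outside its own planted row within reach of any
# detector (margin beyond the largest default cutoff)
check_packing <- function(frame, truth, margin = 5.0) {
  a <- atoms_with_side(frame)
  A <- a[a$side == "receptor", ]
  B <- a[a$side == "ligand", ]
  if (nrow(A) == 0L || nrow(B) == 0L) return(invisible(TRUE))
  pr <- cross_pairs(A, B, margin)
  if (is.null(pr)) return(invisible(TRUE))
  same_row <- A$resno[pr$ia] == B$resno[pr$ib]
  if (!is.null(truth) && nrow(truth) > 0L)
    same_row <- same_row & A$resno[pr$ia] %in%
      as.integer(sub(".*:([0-9]+)$", "\\1", truth$key))
  if (any(!same_row))
    stop("infeasible packing: unplanned cross-side proximity at receptor ",
         "residue ", A$resno[pr$ia[!same_row]][1])
  invisible(TRUE)
}

#' Generate replica frame ensembles with prescribed contact occupancies
#'
#' Builds a toy interface with every planned contact in its on-geometry,
#' then, independently per frame and per contact, switches the contact
#' off with probability `1 - occupancy` by displacing the ligand-side
#' residue along the pair axis to the off-geometry, and adds Gaussian
#' coordinate jitter. On/off margins must clear the detection cutoff by
#' at least `8 * jitter_sd` or the plan is rejected. Deterministic per
#' seed.
#'
#' @param contacts data.frame with columns `type`, `on`, `off`
#'   (on-geometry distance inside the cutoff, off-geometry outside; for
#'   hbonds these are hydrogen-acceptor distances at a 160 degree
#'   planted angle).
#' @param occupancy Target percent occupancies: vector (per contact,
#'   recycled across replicas) or contacts x replicas matrix.
#' @param n_frames Frames per replica (default 350, the snapshot count
#'   analysed per binder replica in the study design).
#' @param n_replicas Replicas (default 4).
#' @param jitter_sd Coordinate jitter standard deviation in Angstrom
#'   (default 0.02).
#' @param params `contact_params` supplying the cutoffs to validate
#'   against.
#' @param seed Integer seed.
#' @return List with `framesets` (named list of `sdp_frameset`), `truth`
#'   (data.frame key/type/replica/target/realized percent) and
#'   `base` (the on-geometry `sdp_frame`).
#' @export
make_ensemble <- function(contacts, occupancy, n_frames = 350,
                          n_replicas = 4, jitter_sd = 0.02,
                          params = contact_params(), seed = 1) {
  contacts <- as.data.frame(contacts)
  nc <- nrow(contacts)
  stopifnot(nc >= 1L, n_frames >= 1L, n_replicas >= 1L)
  occ <- if (is.matrix(occupancy)) occupancy
         else matrix(rep_len(occupancy, nc), nrow = nc, ncol = n_replicas)
  stopifnot(nrow(occ) == nc, ncol(occ) == n_replicas,
            all(occ >= 0), all(occ <= 100))
  cutoff_of <- function(type) switch(type,
    saltbridge = params$saltbridge_cutoff,
    hbond = params$hbond_cutoff,
    hydrophobic = params$hydrophobic_cutoff)
  margin <- 8 * jitter_sd
  for (i in seq_len(nc)) {
    co <- cutoff_of(contacts$type[i])
    if (!(contacts$on[i] < co && co < contacts$off[i]))
      stop("contact ", i, ": need on < cutoff < off (",
           contacts$on[i], " / ", co, " / ", contacts$off[i], ")")
    if (co - contacts$on[i] <= margin || contacts$off[i] - co <= margin)
      stop("jitter sd ", jitter_sd,
           " too large for the on/off margins of contact ", i)
  }
  planted <- lapply(seq_len(nc), function(i) {
    if (contacts$type[i] == "hbond")
      list(type = "hbond", h_a_distance = contacts$on[i], angle = 160)
    else list(type = contacts$type[i], distance = contacts$on[i])
  })
  toy <- make_toy_interface(n_per_side = c(nc, nc), planted = planted)
  base <- toy$frame
  lig_chain <- names(base$sides)[base$sides == "ligand"]
  shift <- contacts$off - contacts$on
  nat <- nrow(base$atoms)
  withr_seed(seed, {
    truth <- NULL
    framesets <- lapply(seq_len(n_replicas), function(r) {
      frames <- vector("list", n_frames)
      on_draws <- matrix(stats::runif(n_frames * nc) < occ[, r] / 100,
                         nrow = nc, byrow = FALSE)
      for (f in seq_len(n_frames)) {
        a <- base$atoms
        for (i in seq_len(nc)) {
          if (!on_draws[i, f]) {
            sel <- a$chain == lig_chain & a$resno == i
            a$x[sel] <- a$x[sel] + shift[i]
          }
        }
        jit <- matrix(stats::rnorm(3 * nat, 0, jitter_sd), ncol = 3)
        a$x <- a$x + jit[, 1]; a$y <- a$y + jit[, 2]; a$z <- a$z + jit[, 3]
        frames[[f]] <- structure(list(atoms = a, sides = base$sides),
                                 class = "sdp_frame")
      }
      truth <<- rbind(truth, data.frame(
        key = toy$truth$key, type = contacts$type,
        replica = paste0("replica", r), target = occ[, r],
        realized = 100 * rowMeans(on_draws), stringsAsFactors = FALSE))
      as_frameset(frames)
    })
    names(framesets) <- paste0("replica", seq_len(n_replicas))
    list(framesets = framesets, truth = truth, base = base)
  })
}

#' Generate a per-residue energy table with planted outliers
#'
#' Baseline electrostatic energies are Gaussian; the listed outlier rows
#' are overwritten with their planted values. `E_total` is the component
#' sum throughout.
#'
#' @param n Residue count (>= 4).
#' @param baseline_mean,baseline_sd E_elec baseline (kcal/mol; defaults
#'   -10 and 1).
#' @param vdw_mean,vdw_sd E_vdw baseline.
#' @param outliers data.frame `(resno, e_elec)` of planted rows; resno
#'   must lie in `1..n`.
#' @param chain Chain id.
#' @param seed Integer seed.
#' @return List with `table` (a `residue_energy_table`) and `truth`
#'   (planted residue numbers).
#' @export
make_energy_table <- function(n = 30, baseline_mean = -10, baseline_sd = 1,
                              vdw_mean = -2, vdw_sd = 0.5, outliers = NULL,
                              chain = "A", seed = 1) {
  stopifnot(n >= 4L)
  if (!is.null(outliers)) {
    outliers <- as.data.frame(outliers)
    if (any(outliers$resno < 1L | outliers$resno > n))
      stop("planted outlier residue out of range 1..", n)
  }
  withr_seed(seed, {
    e_elec <- stats::rnorm(n, baseline_mean, baseline_sd)
    e_vdw <- stats::rnorm(n, vdw_mean, vdw_sd)
    if (!is.null(outliers)) e_elec[outliers$resno] <- outliers$e_elec
    df <- data.frame(chain = chain, resno = seq_len(n), resid = "GLU",
                     e_vdw = e_vdw, e_elec = e_elec,
                     e_total = e_vdw + e_elec, stringsAsFactors = FALSE)
    list(table = structure(df,
                           class = c("residue_energy_table", "data.frame"),
                           model_id = NA, complex_label = "synthetic"),
         truth = if (is.null(outliers)) integer(0) else outliers$resno)
  })
}

#' Write a residue energy table to TSV
#'
#' @param table A `residue_energy_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
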