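#' Element van der Waals radii (Bondi set)
#'
#' @return Named numeric vector of radii in Angstrom; the radii-set name is
#'   carried in the `set` attribute and echoed in SASA results.
#' @export
vdw_radii <- function() {
  structure(c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
              P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
              SE = 1.90),
            set = "bondi")
}

atomic_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
    P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
    SE = 78.971)
}

# Theoretical maximum ASA per residue type (Tien et al. 2013), Angstrom^2;
# used only for the optional "support" class (unbound relative SASA).
max_asa <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
    GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174)
}

guess_element <- function(elety) {
  name <- toupper(gsub("[0-9'\"*]", "", elety))
  two <- c("CL", "BR", "SE", "FE", "MG", "ZN", "NA", "MN")
  ifelse(name %in% two, name, substr(name, 1, 1))
}

#' Construct a single-snapshot complex frame
#'
#' @param atoms data.frame with columns `serial`, `chain`, `resno`, `ins`
#'   (insertion code, `""` if none), `resid` (residue name), `elety` (atom
#'   name), `element`, `x`, `y`, `z`, `o` (occupancy). Missing `element`
#'   is inferred from `elety`; missing `serial`/`ins`/`o` get defaults.
#' @param sides Named character vector mapping chain id to `"receptor"`
#'   or `"ligand"`; every chain present must be assigned.
#' @return An object of class `sdp_frame` (list with `atoms`, `sides`).
#' @export
sdp_frame <- function(atoms, sides) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$elety)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frame")
  sides <- check_sides(atoms$chain, sides)
  structure(list(atoms = atoms, sides = sides), class = "sdp_frame")
}

check_sides <- function(chains, sides) {
  if (is.null(names(sides)) || !all(sides %in% c("receptor", "ligand")))
    stop("sides must be a named chain -> {receptor, ligand} map")
  missing <- setdiff(unique(chains), names(sides))
  if (length(missing) > 0L)
    stop("chain(s) absent from side_spec: ", paste(missing, collapse = ", "))
  for (s in c("receptor", "ligand"))
    if (!any(chains %in% names(sides)[sides == s]))
      stop("no atoms on the ", s, " side")
  sides
}

#' @export
print.sdp_frame <- function(x, ...) {
  cat("Complex frame:", nrow(x$atoms), "atoms;",
      length(unique(x$atoms$chain)), "chains (",
      paste(sprintf("%s:%s", names(x$sides), x$sides), collapse = ", "),
      ")\n")
  invisible(x)
}

atom_key <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety, sep = "|")

residue_key <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$ins, sep = "|")

#' Keep one side of a complex frame
#'
#' @param frame An `sdp_frame`.
#' @param side `"receptor"` or `"ligand"`.
#' @return An `sdp_frame` restricted to that side's chains.
#' @export
frame_side <- function(frame, side = c("receptor", "ligand")) {
  side <- match.arg(side)
  chains <- names(frame$sides)[frame$sides == side]
  atoms <- frame$atoms[frame$atoms$chain %in% chains, , drop = FALSE]
  structure(list(atoms = atoms, sides = frame$sides[frame$sides == side]),
            class = "sdp_frame")
}

pdb_to_atoms <- function(pdb) {
  a <- pdb$atom
  element <- if (!is.null(a$elesy) && any(nzchar(trimws(a$elesy))))
    toupper(trimws(a$elesy)) else guess_element(a$elety)
  element[!nzchar(element) | is.na(element)] <-
    guess_element(a$elety[!nzchar(element) | is.na(element)])
  ins <- a$insert
  ins[is.na(ins)] <- ""
  data.frame(serial = a$eleno, chain = a$chain, resno = a$resno,
             ins = ins, resid = a$resid, elety = a$elety,
             element = element, x = a$x, y = a$y, z = a$z,
             o = ifelse(is.na(a$o), 1, a$o), type = a$type,
             stringsAsFactors = FALSE)
}

#' Read an ordered frame ensemble from PDB input
#'
#' A multi-model PDB file yields one frame per MODEL; a directory yields
#' one frame per `*.pdb` file in lexicographic filename order. Atom
#' ordering is matched across frames by (chain, residue number, insertion
#' code, atom name); a frame missing an atom present in frame 1 (or
#' carrying an extra one) is a topology error.
#'
#' @param path PDB file or directory of PDB files.
#' @param side_spec Named chain -> side map (see [sdp_frame()]).
#' @return An object of class `sdp_frameset`: list with `atoms` (frame-1
#'   atom table), `xyz` (frames x 3N coordinate matrix, bio3d layout)
#'   and `sides`.
#' @export
read_frames <- function(path, side_spec) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) == 0L) stop("no .pdb files in directory: ", path)
    frames <- lapply(files, function(f) {
      pdb <- bio3d::read.pdb(f, verbose = FALSE)
      pdb_to_atoms(pdb)
    })
    ref <- frames[[1]]
    keys <- atom_key(ref)
    xyz <- matrix(NA_real_, nrow = length(frames), ncol = 3L * nrow(ref))
    for (i in seq_along(frames)) {
      fi <- frames[[i]]
      idx <- match(keys, atom_key(fi))
      if (anyNA(idx)) {
        miss <- keys[is.na(idx)][1]
        stop("inconsistent topology: frame ", i, " (", basename(files[i]),
             ") lacks atom ", miss)
      }
      if (nrow(fi) != nrow(ref))
        stop("inconsistent topology: frame ", i, " has ", nrow(fi),
             " atoms, frame 1 has ", nrow(ref))
      xyz[i, ] <- as.vector(t(as.matrix(fi[idx, c("x", "y", "z")])))
    }
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    ref <- pdb_to_atoms(pdb)
    xyz <- matrix(pdb$xyz, ncol = 3L * nrow(ref))
  }
  sides <- check_sides(ref$chain, side_spec)
  structure(list(atoms = ref, xyz = xyz, sides = sides),
            class = "sdp_frameset")
}

#' @export
print.sdp_frameset <- function(x, ...) {
  cat("Frame ensemble:", nrow(x$xyz), "frames x", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a frame set
#' @param frameset An `sdp_frameset`.
#' @return Integer frame count.
#' @export
n_frames <- function(frameset) nrow(frameset$xyz)

#' Extract one frame from a frame set
#'
#' @param frameset An `sdp_frameset`.
#' @param i Frame index (1-based).
#' @return An `sdp_frame`.
#' @export
get_frame <- function(frameset, i) {
  stopifnot(i >= 1L, i <= n_frames(frameset))
  atoms <- frameset$atoms
  m <- matrix(frameset$xyz[i, ], ncol = 3L, byrow = TRUE)
  atoms$x <- m[, 1]; atoms$y <- m[, 2]; atoms$z <- m[, 3]
  structure(list(atoms = atoms, sides = frameset$sides),
            class = "sdp_frame")
}

#' Build a frame set from a list of frames with identical topology
#'
#' @param frames List of `sdp_frame` objects.
#' @return An `sdp_frameset`.
#' @export
as_frameset <- function(frames) {
  ref <- frames[[1]]
  keys <- atom_key(ref$atoms)
  xyz <- t(vapply(frames, function(f) {
    idx <- match(keys, atom_key(f$atoms))
    if (anyNA(idx)) stop("inconsistent topology across frames")
    as.vector(t(as.matrix(f$atoms[idx, c("x", "y", "z")])))
  }, numeric(3L * nrow(ref$atoms))))
  structure(list(atoms = ref$atoms, xyz = xyz, sides = ref$sides),
            class = "sdp_frameset")
}

#' Write a frame or frame set to PDB
#'
#' Frame sets are written as one multi-model file (MODEL/ENDMDL blocks).
#'
#' @param x An `sdp_frame` or `sdp_frameset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path) {
  if (inherits(x, "sdp_frame"))
    x <- structure(list(atoms = x$atoms,
                        xyz = matrix(as.vector(t(as.matrix(
                          x$atoms[, c("x", "y", "z")]))), nrow = 1),
                        sides = x$sides),
                   class = "sdp_frameset")
  a <- x$atoms
  bio3d::write.pdb(file = path, xyz = x$xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = a$serial,
                   elety = a$elety, chain = a$chain, insert = a$ins,
                   o = a$o, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley quadrature)
#'
#' Rolls a probe sphere over the structure by testing, for each atom, a
#' deterministic Fibonacci-spiral quadrature on its expanded sphere
#' (radius = vdW + probe): a point is buried when it falls strictly inside
#' any neighbouring atom's expanded sphere. Per-atom area is the exposed
#' point fraction times `4 * pi * (r_vdw + probe)^2`.
#'
#' @param frame An `sdp_frame`.
#' @param subset `"all"` (default), `"receptor"` or `"ligand"`; the
#'   subset is extracted first, so other atoms do not occlude it.
#' @param probe Probe radius in Angstrom (water = 1.4).
#' @param points Quadrature points per atom (default 960; deterministic
#'   for a fixed count).
#' @param radii Named element -> radius vector; default [vdw_radii()].
#' @param default_radius Radius for elements absent from `radii`; by
#'   default unknown elements are an error.
#' @return An object of class `sasa_result`: list with `atom` (per-atom
#'   data.frame incl. `sasa`), `residue` (per-residue sums), `probe`,
#'   `points`, `radii_set`.
#' @export
sasa <- function(frame, subset = c("all", "receptor", "ligand"),
                 probe = 1.4, points = 960, radii = vdw_radii(),
                 default_radius = NULL) {
  subset <- match.arg(subset)
  if (subset != "all") frame <- frame_side(frame, subset)
  atoms <- frame$atoms
  el <- atoms$element
  r <- unname(radii[el])
  if (anyNA(r)) {
    if (is.null(default_radius))
      stop("unknown element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "),
           " (supply default_radius to accept)")
    r[is.na(r)] <- default_radius
  }
  R <- r + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- sphere_points(points)
  # pairwise squared distances once; neighbours = overlapping expanded spheres
  d2 <- as.matrix(stats::dist(xyz))^2
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    buried <- rep(FALSE, points)
    for (j in nb) {
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      buried <- buried | (dj < R[j]^2)
      if (all(buried)) break
    }
    area[i] <- mean(!buried) * 4 * pi * R[i]^2
  }
  atom_out <- atoms[, c("serial", "chain", "resno", "ins", "resid", "elety",
                        "element")]
  atom_out$sasa <- area
  res <- stats::aggregate(area,
                          by = list(key = residue_key(atoms)), FUN = sum)
  first <- !duplicated(residue_key(atoms))
  res_meta <- atoms[first, c("chain", "resno", "ins", "resid")]
  res_meta$key <- residue_key(atoms)[first]
  residue <- merge(res_meta, res, by = "key", sort = FALSE)
  names(residue)[names(residue) == "x"] <- "sasa"
  structure(list(atom = atom_out, residue = residue, probe = probe,
                 points = points, radii_set = attr(radii, "set")),
            class = "sasa_result")
}

strip_solvent <- function(frame,
                          water = c("HOH", "WAT", "TIP3", "SOL", "TIP"),
                          ions = c("NA", "CL", "K", "MG", "ZN", "CA",
                                   "SOD", "CLA")) {
  a <- frame$atoms
  het <- if (is.null(a$type)) rep(TRUE, nrow(a)) else a$type == "HETATM"
  drop <- a$resid %in% water | (a$resid %in% ions & het)
  if (!is.null(a$type))
    drop <- drop | (het & !a$resid %in% names(max_asa()))
  a <- a[!drop, , drop = FALSE]
  structure(list(atoms = a, sides = frame$sides), class = "sdp_frame")
}

#' Classify interface residues as core / rim (/ support)
#'
#' Computes per-residue SASA for each side in isolation (unbound) and in
#' the complex (bound). Residues losing more than `delta_tol` of area on
#' complexation are interface residues; an interface residue whose burial
#' fraction (delta-SASA over unbound SASA) reaches `core_burial` is core,
#' otherwise rim - unless `emit_support` is set and the residue was
#' already mostly buried free-state (unbound relative SASA below
#' `support_unbound_rsasa`), in which case it is support. Waters, ions
#' and non-protein heteroatoms are stripped first.
#'
#' @param frame An `sdp_frame` with both sides present.
#' @param core_burial Burial fraction threshold for core (default 0.95,
#'   i.e. ">95% buried in the complex").
#' @param delta_tol Minimum delta-SASA in Angstrom^2 counted as interface
#'   (default 0.1; guards quadrature noise).
#' @param support_unbound_rsasa Unbound relative-SASA threshold below
#'   which an interface residue is "support" (default 0.25).
#' @param emit_support Emit the support class (default FALSE: the
#'   two-class core/rim rule).
#' @param probe,points,radii Passed to [sasa()].
#' @return An object of class `interface_classification`: data.frame with
#'   chain, resno, ins, resid, side, unbound, bound, dsasa,
#'   burial_fraction, region; attributes `bsa` (total buried surface
#'   area, both sides) and the thresholds used.
#' @export
classify_interface <- function(frame, core_burial = 0.95, delta_tol = 0.1,
                               support_unbound_rsasa = 0.25,
                               emit_support = FALSE, probe = 1.4,
                               points = 960, radii = vdw_radii()) {
  frame <- strip_solvent(frame)
  bound <- sasa(frame, "all", probe, points, radii)$residue
  per_side <- lapply(c("receptor", "ligand"), function(s)
    cbind(sasa(frame, s, probe, points, radii)$residue, side = s))
  unbound <- do.call(rbind, per_side)
  df <- merge(unbound, bound[, c("key", "sasa")], by = "key",
              suffixes = c("_unbound", "_bound"), sort = FALSE)
  names(df)[names(df) == "sasa_unbound"] <- "unbound"
  names(df)[names(df) == "sasa_bound"] <- "bound"
  df$dsasa <- df$unbound - df$bound
  df$burial_fraction <- ifelse(df$unbound > 0, df$dsasa / df$unbound, 0)
  df$burial_fraction <- pmin(pmax(df$burial_fraction, 0), 1)
  rel_unbound <- df$unbound / unname(max_asa()[df$resid])
  df$region <- "non-interface"
  iface <- df$dsasa > delta_tol
  df$region[iface] <- "rim"
  df$region[iface & df$burial_fraction >= core_burial] <- "core"
  if (emit_support) {
    sup <- iface & df$burial_fraction < core_burial &
      !is.na(rel_unbound) & rel_unbound < support_unbound_rsasa
    df$region[sup] <- "support"
  }
  out <- df[, c("chain", "resno", "ins", "resid", "side", "unbound",
                "bound", "dsasa", "burial_fraction", "region")]
  structure(out,
            class = c("interface_classification", "data.frame"),
            bsa = sum(df$dsasa[iface]),
            core_burial = core_burial, delta_tol = delta_tol,
            support_unbound_rsasa = if (emit_support) support_unbound_rsasa
                                    else NA_real_,
            probe = probe, points = points,
            radii_set = attr(radii, "set"))
}

#' Write an interface classification to TSV
#'
#' @param classification An `interface_classification`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interface_tsv <- function(classification, path) {
  utils::write.table(as.data.frame(classification), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
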