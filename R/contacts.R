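#' Geometric cutoffs for inter-side contact detection
#'
#' Defaults follow the interfacea-style rules: a residue pair is
#' hydrophobic when a cross-side pair of non-polar atoms lies within
#' 4.4 A; a hydrogen bond needs the hydrogen within 2.5 A of the acceptor
#' and a donor-hydrogen-acceptor angle of at least 120 degrees; a salt
#' bridge needs oppositely charged group atoms within 4.0 A. All
#' comparisons are `<=` the cutoff.
#'
#' @param hydrophobic_cutoff,hbond_cutoff,saltbridge_cutoff Distances (A).
#' @param hbond_min_angle Minimum D-H-A angle in degrees (0, 180].
#' @param hbond_mode `"hydrogen-acceptor"` (default; the printed 2.5 A is
#'   geometrically a hydrogen-acceptor distance, matching the D-H-A
#'   triplet language) or `"donor-acceptor"` for hydrogen-free models
#'   (pair with a larger cutoff, e.g. 3.5 A).
#' @param strict_hydrophobic_pairs If TRUE require at least two distinct
#'   cross-side non-polar atom pairs within the cutoff (the alternative
#'   reading of "at least two non-polar atoms"); default FALSE, where the
#'   two non-polar atoms are the two partners of one pair.
#' @param his_positive Count histidine ND1/NE2 as positively charged
#'   (default FALSE: protonation unknown).
#' @param include_termini Count terminal N / OXT charges (default FALSE).
#' @return A `contact_params` list.
#' @export
contact_params <- function(hydrophobic_cutoff = 4.4, hbond_cutoff = 2.5,
                           hbond_min_angle = 120, saltbridge_cutoff = 4.0,
                           hbond_mode = c("hydrogen-acceptor",
                                          "donor-acceptor"),
                           strict_hydrophobic_pairs = FALSE,
                           his_positive = FALSE,
                           include_termini = FALSE) {
  hbond_mode <- match.arg(hbond_mode)
  stopifnot(hydrophobic_cutoff > 0, hbond_cutoff > 0, saltbridge_cutoff > 0,
            hbond_min_angle > 0, hbond_min_angle <= 180)
  structure(list(hydrophobic_cutoff = hydrophobic_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 hbond_min_angle = hbond_min_angle,
                 saltbridge_cutoff = saltbridge_cutoff,
                 hbond_mode = hbond_mode,
                 strict_hydrophobic_pairs = strict_hydrophobic_pairs,
                 his_positive = his_positive,
                 include_termini = include_termini),
            class = "contact_params")
}

#' Atom chemistry tables used by the contact detectors
#'
#' Covers the 20 standard residues: non-polar atoms (carbon/sulfur
#' excluding carbons of charged or amide groups), hydrogen-bond donors and
#' acceptors, and the positively / negatively charged group atoms
#' (Lys NZ; Arg NE/NH1/NH2; optionally His ND1/NE2; Asp OD1/OD2;
#' Glu OE1/OE2; optionally terminal N and O/OXT).
#'
#' @param params A `contact_params` (controls His protonation and termini).
#' @return List with elements `nonpolar_excluded`, `donors`, `acceptors`,
#'   `positive`, `negative` (atom-name tables keyed by residue name where
#'   residue-specific).
#' @export
chemistry_tables <- function(params = contact_params()) {
  donors <- list(
    backbone = "N",
    ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
    TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
    TYR = "OH", CYS = "SG")
  acceptors <- list(
    backbone = c("O", "OXT"),
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
    GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"),
    MET = "SD")
  positive <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (params$his_positive) positive$HIS <- c("ND1", "NE2")
  negative <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  # polar-context carbons excluded from the non-polar set
  nonpolar_excluded <- list(
    backbone = "C",
    ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD", ARG = "CZ")
  list(nonpolar_excluded = nonpolar_excluded, donors = donors,
       acceptors = acceptors, positive = positive, negative = negative)
}

atoms_with_side <- function(frame) {
  a <- frame$atoms
  a$side <- unname(frame$sides[a$chain])
  a$rkey <- residue_key(a)
  a
}

match_table <- function(atoms, tbl) {
  hit <- rep(FALSE, nrow(atoms))
  if (!is.null(tbl$backbone))
    hit <- hit | atoms$elety %in% tbl$backbone
  for (res in setdiff(names(tbl), "backbone"))
    hit <- hit | (atoms$resid == res & atoms$elety %in% tbl[[res]])
  hit
}

empty_contacts <- function() {
  data.frame(type = character(0), chain_a = character(0),
             resno_a = integer(0), ins_a = character(0),
             resid_a = character(0), chain_b = character(0),
             resno_b = integer(0), ins_b = character(0),
             resid_b = character(0), atom_a = character(0),
             atom_b = character(0), distance = numeric(0),
             angle = numeric(0), key = character(0),
             stringsAsFactors = FALSE)
}

# minimal cross-side atom-pair distances, grouped by residue pair;
# A rows are receptor-side atoms, B rows ligand-side atoms.
cross_pairs <- function(A, B, cutoff) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(NULL)
  ax <- as.matrix(A[, c("x", "y", "z")])
  bx <- as.matrix(B[, c("x", "y", "z")])
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * ax %*% t(bx)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  data.frame(ia = hit[, 1], ib = hit[, 2],
             distance = sqrt(d2[hit]), stringsAsFactors = FALSE)
}

contact_rows <- function(type, A, B, pairs, min_pairs = 1L) {
  if (is.null(pairs)) return(empty_contacts())
  grp <- paste(A$rkey[pairs$ia], B$rkey[pairs$ib], sep = "~")
  keep_groups <- names(which(table(grp) >= min_pairs))
  pairs <- pairs[grp %in% keep_groups, , drop = FALSE]
  grp <- grp[grp %in% keep_groups]
  if (nrow(pairs) == 0L) return(empty_contacts())
  best <- tapply(seq_len(nrow(pairs)), grp,
                 function(ix) ix[which.min(pairs$distance[ix])])
  best <- unname(unlist(best))
  ia <- pairs$ia[best]; ib <- pairs$ib[best]
  out <- data.frame(type = type,
                    chain_a = A$chain[ia], resno_a = A$resno[ia],
                    ins_a = A$ins[ia], resid_a = A$resid[ia],
                    chain_b = B$chain[ib], resno_b = B$resno[ib],
                    ins_b = B$ins[ib], resid_b = B$resid[ib],
                    atom_a = A$elety[ia], atom_b = B$elety[ib],
                    distance = pairs$distance[best], angle = NA_real_,
                    stringsAsFactors = FALSE)
  out$key <- contact_key(out)
  out[order(out$key), , drop = FALSE]
}

#' Canonical contact key
#'
#' Formats a contact as `"type:chainA:resnumA-chainB:resnumB"` with the
#' receptor side always first, so keys match across frames, replicas and
#' side orderings. Insertion codes are appended to the residue number.
#'
#' @param contacts A contact data.frame (as returned by the detectors).
#' @return Character vector of keys.
#' @export
contact_key <- function(contacts) {
  resa <- paste0(contacts$resno_a, ifelse(nzchar(contacts$ins_a),
                                          contacts$ins_a, ""))
  resb <- paste0(contacts$resno_b, ifelse(nzchar(contacts$ins_b),
                                          contacts$ins_b, ""))
  sprintf("%s:%s:%s-%s:%s", contacts$type, contacts$chain_a, resa,
          contacts$chain_b, resb)
}

#' Detect inter-side hydrophobic contacts
#'
#' A residue pair is reported when a cross-side pair of non-polar atoms
#' (element C or S outside charged/amide groups) lies within the cutoff
#' (default 4.4 A, `<=`); under `strict_hydrophobic_pairs` two distinct
#' such atom pairs are required. The minimum distance is reported.
#'
#' @param frame An `sdp_frame`.
#' @param params A `contact_params`.
#' @return Contact data.frame (one row per residue pair).
#' @export
detect_hydrophobic <- function(frame, params = contact_params()) {
  chem <- chemistry_tables(params)
  a <- atoms_with_side(frame)
  np <- a$element %in% c("C", "S") & !match_table(a, chem$nonpolar_excluded)
  A <- a[np & a$side == "receptor", , drop = FALSE]
  B <- a[np & a$side == "ligand", , drop = FALSE]
  pairs <- cross_pairs(A, B, params$hydrophobic_cutoff)
  contact_rows("hydrophobic", A, B, pairs,
               min_pairs = if (params$strict_hydrophobic_pairs) 2L else 1L)
}

#' Detect inter-side salt bridges
#'
#' One contact per inter-side (positive-group residue, negative-group
#' residue) pair whose minimum charged-atom distance is within the cutoff
#' (default 4.0 A, `<=`). Symmetric in side order: the receptor residue is
#' always reported first, whichever charge it carries.
#'
#' @param frame An `sdp_frame`.
#' @param params A `contact_params`.
#' @return Contact data.frame.
#' @export
detect_salt_bridges <- function(frame, params = contact_params()) {
  chem <- chemistry_tables(params)
  a <- atoms_with_side(frame)
  pos <- match_table(a, chem$positive)
  neg <- match_table(a, chem$negative)
  if (params$include_termini) {
    first <- !duplicated(a$chain) & a$elety == "N"
    pos <- pos | first
    neg <- neg | a$elety == "OXT"
  }
  out <- rbind(
    contact_rows("saltbridge",
                 a[pos & a$side == "receptor", , drop = FALSE],
                 a[neg & a$side == "ligand", , drop = FALSE],
                 cross_pairs(a[pos & a$side == "receptor", , drop = FALSE],
                             a[neg & a$side == "ligand", , drop = FALSE],
                             params$saltbridge_cutoff)),
    contact_rows("saltbridge",
                 a[neg & a$side == "receptor", , drop = FALSE],
                 a[pos & a$side == "ligand", , drop = FALSE],
                 cross_pairs(a[neg & a$side == "receptor", , drop = FALSE],
                             a[pos & a$side == "ligand", , drop = FALSE],
                             params$saltbridge_cutoff)))
  # a residue pair bridged in both charge directions collapses to min dist
  if (nrow(out) > 1L && anyDuplicated(out$key)) {
    out <- do.call(rbind, lapply(split(out, out$key),
                                 function(g) g[which.min(g$distance), ]))
  }
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Detect inter-side hydrogen bonds
#'
#' In `hydrogen-acceptor` mode (default), reports a donor-H...acceptor
#' triplet when the hydrogen-acceptor distance is within the cutoff
#' (default 2.5 A) and the D-H-A angle reaches the minimum (default 120
#' degrees). Hydrogens are matched to their donor heavy atom by intra-
#' residue covalent distance (<= 1.25 A). In `donor-acceptor` mode the
#' donor-acceptor distance is tested instead and the angle filter applies
#' only when a bonded hydrogen is present.
#'
#' @param frame An `sdp_frame`.
#' @param params A `contact_params`.
#' @return Contact data.frame with the best (smallest-distance) triplet
#'   per residue pair; `angle` holds the D-H-A angle in degrees.
#' @export
detect_hbonds <- function(frame, params = contact_params()) {
  chem <- chemistry_tables(params)
  a <- atoms_with_side(frame)
  don <- which(match_table(a, chem$donors))
  acc <- which(match_table(a, chem$acceptors))
  hyd <- which(a$element == "H")
  if (params$hbond_mode == "hydrogen-acceptor" && length(hyd) == 0L)
    stop("no hydrogens in frame; switch hbond_mode to \"donor-acceptor\" ",
         "with a suitable cutoff")
  # bond hydrogens to donors within the same residue (<= 1.25 A)
  hd <- NULL
  if (length(hyd) > 0L && length(don) > 0L) {
    cand <- merge(data.frame(h = hyd, rkey = a$rkey[hyd]),
                  data.frame(d = don, rkey = a$rkey[don]), by = "rkey")
    if (nrow(cand) > 0L) {
      dd <- sqrt((a$x[cand$h] - a$x[cand$d])^2 +
                   (a$y[cand$h] - a$y[cand$d])^2 +
                   (a$z[cand$h] - a$z[cand$d])^2)
      cand <- cand[dd <= 1.25, , drop = FALSE]
      hd <- cand
    }
  }
  res <- empty_contacts()
  xyz <- as.matrix(a[, c("x", "y", "z")])
  angle_deg <- function(d, h, ac) {
    v1 <- xyz[d, ] - xyz[h, ]
    v2 <- xyz[ac, ] - xyz[h, ]
    cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(pmax(cs, -1), 1)) * 180 / pi
  }
  collect <- function(di, hi, ai, dist) {
    data.frame(type = "hbond", d = di, h = hi, acc = ai,
               distance = dist, stringsAsFactors = FALSE)
  }
  trip <- NULL
  if (params$hbond_mode == "hydrogen-acceptor") {
    if (!is.null(hd) && nrow(hd) > 0L) {
      H <- a[hd$h, , drop = FALSE]
      for (side_a in c("receptor", "ligand")) {
        hs <- which(H$side == side_a)
        as_ <- acc[a$side[acc] != side_a]
        if (length(hs) == 0L || length(as_) == 0L) next
        pr <- cross_pairs(H[hs, , drop = FALSE],
                          a[as_, , drop = FALSE], params$hbond_cutoff)
        if (is.null(pr)) next
        trip <- rbind(trip, collect(hd$d[hs[pr$ia]], hd$h[hs[pr$ia]],
                                    as_[pr$ib], pr$distance))
      }
    }
  } else {
    for (side_a in c("receptor", "ligand")) {
      ds <- don[a$side[don] == side_a]
      as_ <- acc[a$side[acc] != side_a]
      if (length(ds) == 0L || length(as_) == 0L) next
      pr <- cross_pairs(a[ds, , drop = FALSE], a[as_, , drop = FALSE],
                        params$hbond_cutoff)
      if (is.null(pr)) next
      hi <- rep(NA_integer_, nrow(pr))
      if (!is.null(hd) && nrow(hd) > 0L) {
        m <- match(ds[pr$ia], hd$d)
        hi <- hd$h[m]
      }
      trip <- rbind(trip, collect(ds[pr$ia], hi, as_[pr$ib], pr$distance))
    }
  }
  if (is.null(trip) || nrow(trip) == 0L) return(res)
  trip$angle <- vapply(seq_len(nrow(trip)), function(k) {
    if (is.na(trip$h[k])) NA_real_
    else angle_deg(trip$d[k], trip$h[k], trip$acc[k])
  }, numeric(1))
  keep <- is.na(trip$angle) | trip$angle >= params$hbond_min_angle
  trip <- trip[keep, , drop = FALSE]
  if (nrow(trip) == 0L) return(res)
  # orient receptor-side residue first
  rec_first <- a$side[trip$d] == "receptor"
  ia <- ifelse(rec_first, trip$d, trip$acc)
  ib <- ifelse(rec_first, trip$acc, trip$d)
  out <- data.frame(type = "hbond",
                    chain_a = a$chain[ia], resno_a = a$resno[ia],
                    ins_a = a$ins[ia], resid_a = a$resid[ia],
                    chain_b = a$chain[ib], resno_b = a$resno[ib],
                    ins_b = a$ins[ib], resid_b = a$resid[ib],
                    atom_a = a$elety[ia], atom_b = a$elety[ib],
                    distance = trip$distance, angle = trip$angle,
                    stringsAsFactors = FALSE)
  out$key <- contact_key(out)
  best <- tapply(seq_len(nrow(out)), out$key,
                 function(ix) ix[which.min(out$distance[ix])])
  out <- out[unname(unlist(best)), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$key), , drop = FALSE]
}

#' Detect contacts of one or all types
#'
#' @param frame An `sdp_frame`.
#' @param type `"saltbridge"`, `"hbond"`, `"hydrophobic"` or `"all"`.
#' @param params A `contact_params`.
#' @return Contact data.frame (rows from all requested detectors).
#' @export
detect_contacts <- function(frame,
                            type = c("saltbridge", "hbond", "hydrophobic",
                                     "all"),
                            params = contact_params()) {
  type <- match.arg(type)
  if (type == "all") {
    return(rbind(detect_hydrophobic(frame, params),
                 detect_hbonds(frame, params),
                 detect_salt_bridges(frame, params)))
  }
  switch(type,
         saltbridge = detect_salt_bridges(frame, params),
         hbond = detect_hbonds(frame, params),
         hydrophobic = detect_hydrophobic(frame, params))
}
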