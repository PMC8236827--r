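#' Per-contact, per-replica occupancy across frame ensembles
#'
#' For each replica, drops the first `equilibration` frames, detects the
#' requested contact type in every remaining frame and reports, per
#' contact key, the percentage of analysed frames containing it. Keys
#' absent from a replica get 0. Occupancy is invariant to frame order
#' within a replica.
#'
#' @param framesets Named list of `sdp_frameset`, one per replica.
#' @param type Contact type (`"saltbridge"`, `"hbond"`, `"hydrophobic"`).
#' @param params A `contact_params`.
#' @param equilibration Frames to drop per replica: single count or
#'   vector named/ordered like `framesets`.
#' @param watch_keys Optional keys forced into the table even when never
#'   observed (0 rows).
#' @param subsample Optional number of evenly spaced snapshots to analyse
#'   after trimming.
#' @return An object of class `occupancy_table`: numeric matrix (keys x
#'   replicas, percent) with attributes `frames_analyzed`,
#'   `equilibration`, `type` and `meta` (per-key receptor/ligand residue
#'   numbers parsed from the key).
#' @export
occupancy <- function(framesets, type = c("saltbridge", "hbond",
                                          "hydrophobic"),
                      params = contact_params(), equilibration = 0,
                      watch_keys = NULL, subsample = NULL) {
  type <- match.arg(type)
  stopifnot(length(framesets) >= 1L)
  if (is.null(names(framesets)))
    names(framesets) <- paste0("replica", seq_along(framesets))
  equil <- rep_len(equilibration, length(framesets))
  names(equil) <- names(framesets)
  per_rep <- lapply(names(framesets), function(rep) {
    fs <- framesets[[rep]]
    nf <- n_frames(fs)
    if (equil[rep] >= nf)
      stop("replica ", rep, ": no frames left after trimming ",
           equil[rep], " equilibration frames")
    idx <- seq.int(equil[rep] + 1L, nf)
    if (!is.null(subsample) && subsample < length(idx))
      idx <- idx[unique(round(seq(1L, length(idx),
                                  length.out = subsample)))]
    keys <- unlist(lapply(idx, function(i)
      unique(detect_contacts(get_frame(fs, i), type, params)$key)))
    list(n = length(idx), counts = table(keys))
  })
  names(per_rep) <- names(framesets)
  all_keys <- sort(unique(c(unlist(lapply(per_rep, function(x)
    names(x$counts))), watch_keys)))
  m <- matrix(0, nrow = length(all_keys), ncol = length(framesets),
              dimnames = list(all_keys, names(framesets)))
  for (rep in names(framesets)) {
    cnt <- per_rep[[rep]]$counts
    m[names(cnt), rep] <- 100 * as.numeric(cnt) / per_rep[[rep]]$n
  }
  new_occupancy_table(m,
                      frames_analyzed = vapply(per_rep, `[[`, numeric(1), "n"),
                      equilibration = equil, type = type)
}

#' Assemble an occupancy table from a keys-by-replicas matrix
#'
#' Entry point for externally tabulated occupancies (e.g. published
#' per-replica salt-bridge tables). `NA` cells mean "contact never
#' observed" and are stored as 0.
#'
#' @param m Numeric matrix or data.frame, rows = contact keys, columns =
#'   replicas, cells = percent of analysed frames.
#' @param frames_analyzed,equilibration Optional per-replica counts.
#' @param type Contact type label.
#' @param meta Optional per-key data.frame (e.g. receptor/ligand residue
#'   numbers); row order must match `m`.
#' @return An `occupancy_table`.
#' @export
new_occupancy_table <- function(m, frames_analyzed = NULL,
                                equilibration = NULL, type = "saltbridge",
                                meta = NULL) {
  m <- as.matrix(m)
  m[is.na(m)] <- 0
  if (any(m < 0 | m > 100)) stop("occupancies must lie in [0, 100]")
  if (is.null(meta) && !is.null(rownames(m))) {
    parts <- regmatches(rownames(m),
                        regexec("^[^:]+:[^:]+:([0-9]+)[A-Z]?-[^:]+:([0-9]+)",
                                rownames(m)))
    ok <- lengths(parts) == 3L
    meta <- data.frame(key = rownames(m),
                       receptor_res = ifelse(ok, as.integer(
                         vapply(parts, function(p) if (length(p) == 3L)
                           p[2] else NA_character_, character(1))), NA),
                       ligand_res = ifelse(ok, as.integer(
                         vapply(parts, function(p) if (length(p) == 3L)
                           p[3] else NA_character_, character(1))), NA))
  }
  structure(m, class = c("occupancy_table", "matrix"),
            frames_analyzed = frames_analyzed,
            equilibration = equilibration, type = type, meta = meta)
}

#' Write an occupancy table to TSV (key + per-replica percent columns)
#'
#' @param table An `occupancy_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(table, path) {
  df <- data.frame(key = rownames(table), as.data.frame(unclass(table)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stability and consistency classification of contacts
#'
#' A contact is stable in a replica when its occupancy is strictly above
#' the threshold (default ">25%" of the analysed simulation time) and
#' consistent when it is stable in every replica (`require_all`) or in at
#' least one otherwise.
#'
#' @param table An `occupancy_table` (or plain matrix, keys x replicas).
#' @param threshold Occupancy threshold in percent (strict `>`).
#' @param require_all Require stability in all replicas for consistency.
#' @return An object of class `stability_call`: list with `stable`
#'   (logical keys x replicas matrix), `consistent` (named logical),
#'   `occupancy_range` (per-key min/max), `threshold`, `require_all`,
#'   `meta`.
#' @export
classify_stability <- function(table, threshold = 25, require_all = TRUE) {
  m <- as.matrix(unclass(table))
  m[is.na(m)] <- 0
  stable <- m > threshold
  consistent <- if (require_all) apply(stable, 1, all)
                else apply(stable, 1, any)
  structure(list(stable = stable, consistent = consistent,
                 occupancy_range = data.frame(key = rownames(m),
                                              min = apply(m, 1, min),
                                              max = apply(m, 1, max)),
                 threshold = threshold, require_all = require_all,
                 meta = attr(table, "meta")),
            class = "stability_call")
}

#' @export
print.stability_call <- function(x, ...) {
  cat("Stability call (occupancy >", x$threshold, "%,",
      if (x$require_all) "all replicas" else "any replica", "):\n")
  cat("  consistent:", sum(x$consistent), "/", length(x$consistent),
      "contacts\n")
  if (any(x$consistent))
    cat("  ", paste(names(x$consistent)[x$consistent], collapse = ", "),
        "\n")
  invisible(x)
}

#' Consistent contact keys from a stability call
#'
#' @param call A `stability_call`.
#' @return Character vector of keys stable in every replica.
#' @export
consistent_keys <- function(call) names(call$consistent)[call$consistent]

#' Per-frame RMSD to the ensemble average structure
#'
#' Two passes: all frames are least-squares superposed onto frame 1 over
#' the selection and averaged; each frame is then superposed onto the
#' average and its RMSD over the selection reported.
#'
#' @param frameset An `sdp_frameset` with >= 2 frames.
#' @param selection Optional atom selection: integer indices into the
#'   atom table, a logical vector, or a predicate `function(atoms)`
#'   returning one. Default: all atoms.
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return Numeric per-frame RMSD vector with attribute `units`.
#' @export
rmsd_to_average <- function(frameset, selection = NULL,
                            units = c("angstrom", "nm")) {
  units <- match.arg(units)
  if (n_frames(frameset) < 2L) stop("need at least 2 frames")
  sel <- resolve_selection(frameset$atoms, selection)
  if (length(sel) == 0L) stop("empty atom selection")
  inds <- bio3d::atom2xyz(sel)
  xyz <- frameset$xyz
  fit1 <- bio3d::fit.xyz(fixed = xyz[1, ], mobile = xyz,
                         fixed.inds = inds, mobile.inds = inds)
  avg <- colMeans(fit1)
  fit2 <- bio3d::fit.xyz(fixed = avg, mobile = fit1,
                         fixed.inds = inds, mobile.inds = inds)
  r <- bio3d::rmsd(avg, fit2, a.inds = inds, b.inds = inds, fit = FALSE)
  if (units == "nm") r <- r / 10
  structure(as.numeric(r), units = units)
}

resolve_selection <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.function(selection)) selection <- selection(atoms)
  if (is.logical(selection)) selection <- which(selection)
  as.integer(selection)
}

#' Radius of gyration of a frame
#'
#' `Rg = sqrt( sum m_i |r_i - r_cm|^2 / sum m_i )`, mass-weighted by
#' default (element masses; unit masses otherwise).
#'
#' @param frame An `sdp_frame` with >= 1 atom.
#' @param mass_weighted Use atomic masses (default TRUE).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, mass_weighted = TRUE) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  stopifnot(nrow(xyz) >= 1L)
  m <- if (mass_weighted) {
    mm <- atomic_masses()[frame$atoms$element]
    if (anyNA(mm)) stop("unknown element(s) for mass lookup: ",
                        paste(unique(frame$atoms$element[is.na(mm)]),
                              collapse = ", "))
    unname(mm)
  } else rep(1, nrow(xyz))
  cm <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(xyz, 2, cm)^2)) / sum(m))
}

#' Box-and-whisker summary of per-frame contact counts
#'
#' Quartiles by linear interpolation (type 7); whiskers at
#' `Q1 - mult*IQR` and `Q3 + mult*IQR` (default mult 2); outliers are
#' values strictly outside the whiskers. When a second condition is given
#' the association `r` is the Pearson correlation of the two aligned
#' per-frame series when their lengths match, else of their percentile
#' profiles (101 evenly spaced quantiles).
#'
#' @param countsA Numeric per-frame counts (>= 4 values).
#' @param countsB Optional second condition.
#' @param whisker_iqr_mult Whisker length in IQR units (default 2).
#' @return An object of class `distribution_summary`: list with per-
#'   condition `quartiles`, `iqr`, `whiskers`, `outliers`, plus `r` and
#'   `r_method` when two conditions are given.
#' @export
distribution_summary <- function(countsA, countsB = NULL,
                                 whisker_iqr_mult = 2) {
  one <- function(x) {
    if (length(x) < 4L) stop("need at least 4 values per condition")
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- q[1] - whisker_iqr_mult * iqr
    hi <- q[3] + whisker_iqr_mult * iqr
    list(quartiles = stats::setNames(q, c("Q1", "median", "Q3")),
         iqr = iqr, whiskers = c(lower = lo, upper = hi),
         outliers = x[x < lo | x > hi])
  }
  out <- list(A = one(countsA), whisker_iqr_mult = whisker_iqr_mult)
  if (!is.null(countsB)) {
    out$B <- one(countsB)
    if (length(countsA) == length(countsB)) {
      out$r <- stats::cor(countsA, countsB)
      out$r_method <- "pearson_aligned_series"
    } else {
      p <- seq(0, 1, length.out = 101)
      out$r <- stats::cor(stats::quantile(countsA, p, type = 7),
                          stats::quantile(countsB, p, type = 7))
      out$r_method <- "pearson_quantile_profiles"
    }
  }
  structure(out, class = "distribution_summary")
}

#' Per-frame contact counts for a frame ensemble
#'
#' @param frameset An `sdp_frameset`.
#' @param type Contact type.
#' @param params A `contact_params`.
#' @param equilibration Frames to drop first.
#' @return Integer vector of per-frame contact counts.
#' @export
contact_counts <- function(frameset, type = "saltbridge",
                           params = contact_params(), equilibration = 0) {
  idx <- seq.int(equilibration + 1L, n_frames(frameset))
  vapply(idx, function(i)
    nrow(detect_contacts(get_frame(frameset, i), type, params)), integer(1))
}
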