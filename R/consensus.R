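#' Candidate SDP set
#'
#' A set of receptor residue positions (reference numbering) with residue
#' letters and per-position provenance (which stage/method proposed it).
#'
#' @param pos Integer residue numbers.
#' @param letter Residue letters (single characters, `NA` allowed).
#' @param provenance Character provenance tag(s), recycled.
#' @return A `candidate_set` data.frame: pos, letter, provenance,
#'   unresolved (logical, positions absent from the structure numbering).
#' @export
candidate_set <- function(pos, letter = NA_character_,
                          provenance = "user") {
  pos <- as.integer(pos)
  df <- data.frame(pos = pos,
                   letter = rep_len(as.character(letter), length(pos)),
                   provenance = rep_len(as.character(provenance),
                                        length(pos)),
                   unresolved = rep_len(FALSE, length(pos)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("candidate_set", "data.frame"))
}

merge_provenance <- function(a, b) {
  paste(unique(unlist(strsplit(c(a, b), ";"))), collapse = ";")
}

#' Keep candidates located in given interface regions
#'
#' Filters a candidate set by the region label of the matching
#' receptor-side residue in an interface classification (default: keep
#' rim only, where partner-selecting SDPs are expected to sit). A
#' candidate whose position is absent from the structure numbering is
#' retained but flagged `unresolved` and excluded from any final verdict.
#'
#' @param candidates A `candidate_set`.
#' @param classification An `interface_classification`, or a bare integer
#'   vector of receptor residue numbers to treat as the kept region.
#' @param keep Regions to keep (default `"rim"`).
#' @return Filtered `candidate_set` with provenance annotated.
#' @export
rim_filter <- function(candidates, classification, keep = "rim") {
  if (inherits(classification, "interface_classification") ||
      is.data.frame(classification)) {
    cls <- as.data.frame(classification)
    cls <- cls[cls$side == "receptor", , drop = FALSE]
    region <- cls$region[match(candidates$pos, cls$resno)]
  } else {
    region <- ifelse(candidates$pos %in% as.integer(classification),
                     keep[1], "non-interface")
  }
  unresolved <- is.na(region)
  ok <- !unresolved & region %in% keep
  out <- candidates[ok | unresolved, , drop = FALSE]
  out$unresolved <- unresolved[ok | unresolved]
  out$provenance <- ifelse(out$unresolved, out$provenance,
                           paste0(out$provenance, ";rim_filter"))
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"))
}

#' Receptor residues forming consistent salt bridges
#'
#' Turns a stability call into a candidate set: the receptor-side residue
#' numbers of every contact consistent across replicas. Residue numbers
#' come from the call's metadata when present, else are parsed from the
#' canonical contact keys.
#'
#' @param calls A `stability_call` computed on receptor-ligand contact
#'   keys.
#' @param letters Optional named letters (names = residue numbers).
#' @return A `candidate_set` with the consistent keys recorded in
#'   attribute `keys` (named by position).
#' @export
saltbridge_former_filter <- function(calls, letters = NULL) {
  keys <- consistent_keys(calls)
  if (length(keys) == 0L) {
    out <- candidate_set(integer(0))
    attr(out, "keys") <- character(0)
    return(out)
  }
  meta <- calls$meta
  res <- if (!is.null(meta) && all(keys %in% meta$key))
    meta$receptor_res[match(keys, meta$key)]
  else
    as.integer(sub("^[^:]+:[^:]+:([0-9]+).*$", "\\1", keys))
  if (anyNA(res))
    stop("cannot resolve receptor residue for key(s): ",
         paste(keys[is.na(res)], collapse = ", "))
  pos <- sort(unique(res))
  lt <- if (is.null(letters)) NA_character_
        else unname(letters[as.character(pos)])
  out <- candidate_set(pos, letter = lt, provenance = "consistent_saltbridge")
  attr(out, "keys") <- stats::setNames(keys, res)
  out
}

#' Remove candidates also evidenced in the negative control
#'
#' Positions carrying the same evidence in the non-binder (control)
#' complex cannot be partner-selecting; they are dropped from the target
#' set.
#'
#' @param target,control `candidate_set`s in the same receptor numbering
#'   (bare integer vectors accepted).
#' @return Filtered `candidate_set`.
#' @export
negative_control_elimination <- function(target, control) {
  if (!inherits(target, "candidate_set")) target <- candidate_set(target)
  cpos <- if (inherits(control, "candidate_set") || is.data.frame(control))
    control$pos else as.integer(control)
  out <- target[!target$pos %in% cpos, , drop = FALSE]
  out$provenance <- paste0(out$provenance, ";control_eliminated")
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            keys = attr(target, "keys"))
}

#' Keep candidates whose residue differs from every other paralog
#'
#' A position can only be partner-selecting for the reference paralog if
#' its residue letter is substituted in the other paralogs: a candidate is
#' dropped when its letter equals the letter of any other paralog at that
#' position (per-letter equality; conservative substitutions such as E/D
#' count as different). Gaps and absent rows never match; candidates
#' without a paralog-map row are kept but flagged `unresolved`.
#'
#' @param candidates A `candidate_set`; letters are taken from the map's
#'   `ref` column when the candidate letter is `NA`.
#' @param pmap Paralog residue map: data.frame with columns `pos`, `ref`
#'   (reference-paralog letter) and one letter column per other paralog
#'   (see [tam_paralog_map()] for the packaged example).
#' @param mode Only `"any_other_identical_drops"` is implemented.
#' @return Filtered `candidate_set`.
#' @export
paralog_uniqueness <- function(candidates, pmap,
                               mode = "any_other_identical_drops") {
  stopifnot(identical(mode, "any_other_identical_drops"))
  pmap <- as.data.frame(pmap)
  stopifnot(all(c("pos", "ref") %in% names(pmap)))
  other_cols <- setdiff(names(pmap), c("pos", "ref"))
  row <- match(candidates$pos, pmap$pos)
  letter <- candidates$letter
  letter[is.na(letter)] <- pmap$ref[row][is.na(letter)]
  shared <- rep(FALSE, nrow(candidates))
  for (cc in other_cols) {
    ol <- pmap[[cc]][row]
    shared <- shared | (!is.na(ol) & ol != "-" & nzchar(ol) &
                          !is.na(letter) & ol == letter)
  }
  unresolved <- is.na(row)
  out <- candidates[(!shared & !unresolved) | unresolved, , drop = FALSE]
  out$letter <- letter[(!shared & !unresolved) | unresolved]
  out$unresolved <- out$unresolved | unresolved[(!shared & !unresolved) |
                                                  unresolved]
  out$provenance <- ifelse(out$unresolved, out$provenance,
                           paste0(out$provenance, ";paralog_unique"))
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            keys = attr(candidates, "keys"))
}

#' Flag candidates conserved across orthologs
#'
#' A candidate position is conserved when the modal residue frequency of
#' its alignment column (in a single-group ortholog alignment containing
#' the reference) reaches `min_identity`.
#'
#' @param candidates A `candidate_set`.
#' @param ortholog_alignment An `sdp_alignment` of orthologs.
#' @param reference_id Reference record id within that alignment.
#' @param min_identity Modal-frequency threshold (default 1.0, strict
#'   conservation).
#' @return Named logical vector (names = positions); `NA` for positions
#'   without a mapped column.
#' @export
ortholog_conservation <- function(candidates, ortholog_alignment,
                                  reference_id, min_identity = 1.0) {
  if (nrow(candidates) == 0L)
    return(stats::setNames(logical(0), character(0)))
  pm <- map_columns_to_reference(ortholog_alignment, reference_id)
  inv <- invert_position_map(pm)
  cols <- inv[as.character(candidates$pos)]
  m <- alignment_matrix(ortholog_alignment)
  flag <- vapply(cols, function(cl) {
    if (is.na(cl)) return(NA)
    tab <- table(m[, cl])
    max(tab) / sum(tab) >= min_identity
  }, logical(1))
  stats::setNames(flag, candidates$pos)
}

#' Build the final SDP report
#'
#' Composes the evidence stages into per-candidate flags and a final
#' verdict. A position gets a positive verdict only when it (i) sits at
#' the interface rim of the binder complex (when rim evidence is
#' supplied), (ii) forms a salt bridge consistently across all binder
#' replicas, (iii) carries no such evidence in the negative-control
#' complex, (iv) is paralog-unique, and (v) is resolved in every supplied
#' evidence source. Ortholog conservation is reported as supporting
#' evidence. Sequence-stage candidates are echoed with union and
#' all-method-agreement views.
#'
#' @param binder_calls `stability_call` for the binder complex
#'   (required).
#' @param control_calls Optional `stability_call` for the non-binder
#'   control.
#' @param paralog_map Optional paralog residue map (see
#'   [paralog_uniqueness()]).
#' @param interface Optional `interface_classification` of the binder
#'   complex, or integer vector of rim residue numbers.
#' @param sequence_candidates Optional named list of `candidate_set`s,
#'   one per sequence-stage method.
#' @param ortholog_alignment,reference_id Optional ortholog alignment
#'   and its reference record for the conservation flag.
#' @param metadata Named list echoed into the report (thresholds, seeds,
#'   interpretation decisions).
#' @return An object of class `sdp_report`: list with `candidates`
#'   (per-position evidence data.frame incl. `verdict`), `verdict`
#'   (integer positions), `sequence` (union/agreement views) and
#'   `metadata`.
#' @export
build_report <- function(binder_calls, control_calls = NULL,
                         paralog_map = NULL, interface = NULL,
                         sequence_candidates = NULL,
                         ortholog_alignment = NULL, reference_id = NULL,
                         metadata = list()) {
  if (is.null(binder_calls) && is.null(sequence_candidates))
    stop("no evidence at all: supply binder_calls or sequence_candidates")
  md <- c(list(stability_threshold = if (!is.null(binder_calls))
    binder_calls$threshold else NA,
    require_all_replicas = if (!is.null(binder_calls))
      binder_calls$require_all else NA), metadata)

  cand <- if (!is.null(binder_calls)) {
    letters <- NULL
    if (!is.null(paralog_map))
      letters <- stats::setNames(paralog_map$ref,
                                 as.character(paralog_map$pos))
    saltbridge_former_filter(binder_calls, letters = letters)
  } else candidate_set(integer(0))
  keys <- attr(cand, "keys")

  df <- as.data.frame(cand)
  df$saltbridge_consistent <- rep(TRUE, nrow(df))
  df$saltbridge_keys <- vapply(df$pos, function(p)
    paste(keys[names(keys) == as.character(p)], collapse = ","),
    character(1))

  df$shared_with_control <- rep(FALSE, nrow(df))
  if (!is.null(control_calls)) {
    ctrl <- saltbridge_former_filter(control_calls)
    df$shared_with_control <- df$pos %in% ctrl$pos
    md$control_positions <- ctrl$pos
  }

  df$paralog_unique <- rep(NA, nrow(df))
  if (!is.null(paralog_map)) {
    uniq <- paralog_uniqueness(cand, paralog_map)
    row <- match(df$pos, as.data.frame(paralog_map)$pos)
    df$paralog_unique <- df$pos %in% uniq$pos[!uniq$unresolved]
    df$paralog_unique[is.na(row)] <- NA
  }

  df$rim <- rep(NA, nrow(df))
  if (!is.null(interface)) {
    rf <- rim_filter(cand, interface)
    df$rim <- df$pos %in% rf$pos[!rf$unresolved]
    if (inherits(interface, "interface_classification") ||
        is.data.frame(interface)) {
      cls <- as.data.frame(interface)
      cls <- cls[cls$side == "receptor", , drop = FALSE]
      df$rim[!df$pos %in% cls$resno] <- NA
    }
  }

  df$ortholog_conserved <- rep(NA, nrow(df))
  if (!is.null(ortholog_alignment)) {
    oc <- ortholog_conservation(cand, ortholog_alignment, reference_id)
    df$ortholog_conserved <- unname(oc[as.character(df$pos)])
  }

  df$unresolved <- (!is.null(interface) & is.na(df$rim)) |
    (!is.null(paralog_map) & is.na(df$paralog_unique))
  rim_ok <- if (is.null(interface)) TRUE else isTRUE_vec(df$rim)
  par_ok <- if (is.null(paralog_map)) TRUE else isTRUE_vec(df$paralog_unique)
  df$verdict <- df$saltbridge_consistent & !df$shared_with_control &
    rim_ok & par_ok

  seq_view <- NULL
  if (!is.null(sequence_candidates)) {
    sets <- lapply(sequence_candidates, function(s) s$pos)
    all_pos <- sort(unique(unlist(sets)))
    agree <- vapply(all_pos, function(p)
      sum(vapply(sets, function(s) p %in% s, logical(1))), integer(1))
    seq_view <- list(per_method = sets,
                     union = all_pos,
                     agreement = stats::setNames(agree, all_pos),
                     agreed_by_all = all_pos[agree == length(sets)])
  }

  structure(list(candidates = df,
                 verdict = sort(df$pos[df$verdict]),
                 sequence = seq_view,
                 metadata = md),
            class = "sdp_report")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.sdp_report <- function(x, ...) {
  cat("SDP report:", nrow(x$candidates), "candidate position(s)\n")
  cat("  final verdict:",
      if (length(x$verdict)) paste(x$verdict, collapse = ", ") else "none",
      "\n")
  if (!is.null(x$sequence))
    cat("  sequence-stage union:",
        paste(x$sequence$union, collapse = ", "),
        "| agreed by all:",
        paste(x$sequence$agreed_by_all, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise an SDP report to JSON and TSV
#'
#' Writes `report.json` (stable key order) and `candidates.tsv` into
#' `dir`.
#'
#' @param report An `sdp_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(candidates = report$candidates, verdict = report$verdict,
         sequence = report$sequence, metadata = report$metadata),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE)
  utils::write.table(report$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
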