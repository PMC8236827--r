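#' Amino-acid alphabet used by the column scorers
#'
#' The 20 standard amino acids, the gap symbol `-` (deletions can be
#' group-specific, so gaps are scored like any other symbol) and `X`
#' (unknown residue, common in raw UniProt pulls).
#'
#' @return Character vector of 22 single-letter symbols.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
    "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "-")
}

new_alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  structure(list(ids = ids, seqs = seqs, length = nchar(seqs[1])),
            class = "sdp_alignment")
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or Clustal alignments into an `sdp_alignment`. Sequences are
#' uppercased and the `.` gap character is normalised to `-`. All records
#' must have identical aligned length and unique identifiers; symbols other
#' than the 20 amino acids, `X` and gaps are rejected.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return An object of class `sdp_alignment` with elements `ids`, `seqs`
#'   (aligned, uppercase, `-` gaps) and `length` (column count).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (file.size(path) == 0L || !any(nzchar(trimws(readLines(path, warn = FALSE)))))
    stop("empty alignment file: ", path)
  if (format == "fasta") {
    aln <- seqinr::read.alignment(path, format = "fasta",
                                  forceToLower = FALSE)
    if (aln$nb < 1L) stop("empty alignment file: ", path)
    ids <- as.character(aln$nam)
    seqs <- as.character(aln$seq)
  } else {
    # block-structured Clustal; parsed here because the interleaved
    # blocks (with or without conservation lines) accumulate per id
    lines <- readLines(path, warn = FALSE)
    if (!grepl("^(CLUSTAL|MUSCLE)", lines[1]))
      stop("not a Clustal file (missing CLUSTAL header): ", path)
    body <- lines[-1]
    body <- body[nzchar(trimws(body)) & !grepl("^\\s", body)]
    if (length(body) == 0L) stop("empty alignment file: ", path)
    toks <- strsplit(trimws(body), "[[:space:]]+")
    ids_all <- vapply(toks, `[`, "", 1)
    chunk <- vapply(toks, `[`, "", 2)
    ids <- unique(ids_all)
    seqs <- vapply(ids, function(i)
      paste(chunk[ids_all == i], collapse = ""), "")
  }
  seqs <- gsub("[\r\n ]", "", seqs)
  as_alignment(ids, seqs)
}

#' Construct an alignment from identifiers and aligned sequences
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of aligned sequences (same length each).
#' @return An `sdp_alignment`.
#' @export
as_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(gsub(".", "-", as.character(seqs), fixed = TRUE))
  if (length(ids) == 0L) stop("empty alignment: no records")
  if (anyDuplicated(ids))
    stop("duplicate record identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop("alignment shape error: ragged row lengths (",
         paste(range(len), collapse = "-"), ")")
  if (len[1] < 1L) stop("alignment shape error: zero-length records")
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 aa_alphabet())
  if (length(bad) > 0L)
    stop("symbol error: non-amino-acid letter(s) in alignment: ",
         paste(bad, collapse = ", "))
  new_alignment(ids, seqs)
}

#' @export
print.sdp_alignment <- function(x, ...) {
  cat("Multiple sequence alignment:", length(x$ids), "records x",
      x$length, "columns\n")
  invisible(x)
}

#' Write an alignment to FASTA or Clustal format
#'
#' @param alignment An `sdp_alignment`.
#' @param path Output file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    seqinr::write.fasta(as.list(alignment$seqs), names = alignment$ids,
                        file.out = path, nbchar = 60)
  } else {
    # fixed-block Clustal layout, 60 columns per block
    ids <- alignment$ids
    width <- max(nchar(ids)) + 3L
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("CLUSTAL W multiple sequence alignment\n", con)
    starts <- seq(1L, alignment$length, by = 60L)
    for (s in starts) {
      e <- min(s + 59L, alignment$length)
      chunk <- substr(alignment$seqs, s, e)
      writeLines(sprintf("%-*s%s", width, ids, chunk), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Matrix view of an alignment
#'
#' @param alignment An `sdp_alignment`.
#' @return Character matrix (records x columns) with row names = ids.
#' @export
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$seqs, ""))
  rownames(m) <- alignment$ids
  m
}

#' Partition alignment records into named specificity groups
#'
#' Every record must be assigned to exactly one group: unknown identifiers,
#' overlapping groups, empty groups and unassigned records are all errors
#' (no silent drop).
#'
#' @param alignment An `sdp_alignment`.
#' @param group_spec Named list mapping group name to a character vector of
#'   record identifiers, or a two-column data.frame `(id, group)`.
#' @return An object of class `sdp_grouped` with elements `alignment`,
#'   `groups` (named list of id vectors) and `N` (group count).
#' @export
assign_groups <- function(alignment, group_spec) {
  if (is.data.frame(group_spec)) {
    stopifnot(ncol(group_spec) >= 2L)
    group_spec <- split(as.character(group_spec[[1]]),
                        as.character(group_spec[[2]]))
  }
  if (is.null(names(group_spec)) || any(!nzchar(names(group_spec))))
    stop("group_spec must be a named list of identifier vectors")
  ids <- unlist(group_spec, use.names = FALSE)
  unknown <- setdiff(ids, alignment$ids)
  if (length(unknown) > 0L)
    stop("unknown identifier(s) in group_spec: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(ids))
    stop("overlapping groups: record(s) listed more than once: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- names(group_spec)[lengths(group_spec) == 0L]
  if (length(empty) > 0L)
    stop("empty group(s): ", paste(empty, collapse = ", "))
  missing <- setdiff(alignment$ids, ids)
  if (length(missing) > 0L)
    stop("record(s) absent from group_spec: ",
         paste(missing, collapse = ", "))
  if (length(group_spec) < 2L) stop("at least 2 groups are required")
  structure(list(alignment = alignment,
                 groups = lapply(group_spec, as.character),
                 N = length(group_spec)),
            class = "sdp_grouped")
}

#' @export
print.sdp_grouped <- function(x, ...) {
  cat("Grouped alignment:", length(x$alignment$ids), "records x",
      x$alignment$length, "columns;", x$N, "groups (",
      paste(sprintf("%s:%d", names(x$groups), lengths(x$groups)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Read a two-column group specification TSV
#'
#' Expected columns: identifier, group name (header optional, detected when
#' the first line is `id<TAB>group`).
#'
#' @param path Path to the TSV file.
#' @return Named list of identifier vectors suitable for [assign_groups()].
#' @export
read_group_spec <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (identical(tolower(as.character(df[1, 1:2])), c("id", "group")))
    df <- df[-1, , drop = FALSE]
  split(as.character(df[[1]]), as.character(df[[2]]))
}

#' Map alignment columns to reference-sequence residue numbering
#'
#' Column `c` maps to the count of non-gap reference characters in columns
#' `1..c` when the reference character at `c` is not a gap; columns where
#' the reference is gapped are unmapped. Both columns and residue numbers
#' are 1-based, so SDPs can be reported in reference numbering ("R48").
#'
#' @param grouped An `sdp_grouped` (or plain `sdp_alignment`).
#' @param reference_id Identifier of the reference record.
#' @return An object of class `position_map`: an integer vector of residue
#'   numbers named by the (character) column index, with attributes
#'   `reference_id` and `reference_letters`.
#' @export
map_columns_to_reference <- function(grouped, reference_id) {
  alignment <- if (inherits(grouped, "sdp_grouped")) grouped$alignment else grouped
  i <- match(reference_id, alignment$ids)
  if (is.na(i)) stop("unknown reference id: ", reference_id)
  chars <- strsplit(alignment$seqs[i], "")[[1]]
  notgap <- chars != "-"
  if (!any(notgap)) {
    warning("reference record is all gaps; empty position map")
    pm <- integer(0)
  } else {
    pm <- cumsum(notgap)[notgap]
    names(pm) <- which(notgap)
  }
  structure(pm, class = "position_map", reference_id = reference_id,
            reference_letters = chars[notgap])
}

#' Invert a position map (residue number to alignment column)
#'
#' @param pmap A `position_map`.
#' @return Integer vector of columns named by residue number.
#' @export
invert_position_map <- function(pmap) {
  out <- as.integer(names(pmap))
  names(out) <- as.character(unclass(pmap))
  out
}
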