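fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "sdpmapper")
  if (!nzchar(p)) stop("packaged fixture not found: ", name)
  p
}

#' Published per-replica salt-bridge occupancies of the Axl complexes
#'
#' Transcription of the reported salt-bridge occupancy tables for the
#' Axl:Gas6 (binder) and Axl:Pros1 (non-binder control) complexes: for
#' each salt bridge (SB label, receptor and ligand residue numbers), the
#' percentage of analysed frames containing it in each of four
#' independent MD replicas. Dashes in the source (contact never
#' observed) are stored as 0.
#'
#' @param complex `"gas6"` or `"pros1"`.
#' @return An `occupancy_table` (rows = SB labels) whose `meta`
#'   attribute carries the receptor (`receptor_res`) and ligand
#'   (`ligand_res`) residue numbers.
#' @export
axl_occupancy_fixture <- function(complex = c("gas6", "pros1")) {
  complex <- match.arg(complex)
  df <- utils::read.table(
    fixture_path(sprintf("axl_%s_sb_occupancy.tsv", complex)),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  reps <- grep("^replica", names(df), value = TRUE)
  m <- as.matrix(df[, reps])
  rownames(m) <- df$sb
  meta <- data.frame(key = df$sb, receptor_res = df$axl_res,
                     ligand_res = df[[3]])
  new_occupancy_table(m, type = "saltbridge", meta = meta)
}

#' Paralog residue correspondence at the candidate Axl positions
#'
#' The residue letters found in Tyro3 and Mer at the alignment positions
#' of the candidate Axl SDPs (reference letters in column `ref`); `-`
#' marks a gap.
#'
#' @return Data.frame with columns `pos`, `ref`, `tyro3`, `mer`, usable
#'   directly with [paralog_uniqueness()].
#' @export
tam_paralog_map <- function() {
  utils::read.table(fixture_path("tam_paralog_positions.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "character"))
}

#' Salt-bridge pairs proposed by the refinement (HADDOCK) stage
#'
#' The six receptor:ligand salt bridges identified from refined Axl:Gas6
#' models, keyed SB1-SB6.
#'
#' @return Data.frame with columns `sb`, `axl_res`, `ligand_res`.
#' @export
axl_refinement_pairs <- function() {
  utils::read.table(fixture_path("axl_refinement_saltbridges.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Rim-filtered sequence-stage SDP candidates for Axl
#'
#' The positions proposed by the three sequence scorers that fall on the
#' Axl:Gas6 interface rim.
#'
#' @return Named list of `candidate_set`s (one per method).
#' @export
axl_sequence_candidates <- function() {
  df <- utils::read.table(fixture_path("axl_sequence_candidates.tsv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$method), function(g)
    candidate_set(g$pos, g$letter, provenance = g$method[1]))
}
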