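#' Read a per-residue interaction-energy table
#'
#' Two dialects: `haddock_disp`, the whitespace-separated per-residue
#' energy listing written by refinement runs (comment/header lines start
#' with `#`; columns chain, residue number, residue name, E_vdw, E_elec,
#' E_total, kcal/mol; see the packaged example
#' `extdata/example-ene-residue.disp`), and `tsv`, a column-named
#' tab-separated file with (case-insensitive) columns `chain`, `resno`,
#' `resid`, `e_vdw`, `e_elec`, `e_total`. Missing components stay `NA`,
#' never 0. Rows violating `E_total = E_vdw + E_elec` by more than 0.1
#' kcal/mol raise a warning; duplicated (chain, resno) keys are an error.
#'
#' @param path Input file.
#' @param dialect `"haddock_disp"` or `"tsv"`.
#' @param model_id,complex_label Optional labels carried as attributes.
#' @return A `residue_energy_table` data.frame: chain, resno, resid,
#'   e_vdw, e_elec, e_total.
#' @export
read_residue_energies <- function(path, dialect = c("haddock_disp", "tsv"),
                                  model_id = NA, complex_label = NA) {
  dialect <- match.arg(dialect)
  if (dialect == "haddock_disp") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (length(lines) == 0L) stop("no parseable rows in ", path)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    bad <- lengths(parts) < 6L
    if (any(bad)) stop("malformed row(s) in ", path, ": ",
                       lines[bad][1])
    df <- data.frame(chain = vapply(parts, `[`, "", 1),
                     resno = as.integer(vapply(parts, `[`, "", 2)),
                     resid = vapply(parts, `[`, "", 3),
                     e_vdw = as.numeric(vapply(parts, `[`, "", 4)),
                     e_elec = as.numeric(vapply(parts, `[`, "", 5)),
                     e_total = as.numeric(vapply(parts, `[`, "", 6)),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    need <- c("chain", "resno", "resid", "e_vdw", "e_elec", "e_total")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0L)
      stop("tsv energy table lacks column(s): ",
           paste(missing, collapse = ", "))
    df <- df[, need]
  }
  if (nrow(df) == 0L) stop("no parseable rows in ", path)
  key <- paste(df$chain, df$resno)
  if (anyDuplicated(key))
    stop("duplicated residue key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  ok <- !is.na(df$e_vdw) & !is.na(df$e_elec) & !is.na(df$e_total)
  off <- ok & abs(df$e_total - (df$e_vdw + df$e_elec)) > 0.1
  if (any(off))
    warning("E_total != E_vdw + E_elec (>0.1 kcal/mol) for ",
            sum(off), " row(s)")
  structure(df, class = c("residue_energy_table", "data.frame"),
            model_id = model_id, complex_label = complex_label)
}

#' Model-ranking score weights
#'
#' The weighted sum used to rank refined complex models:
#' `1.0*E_vdw + 0.2*E_elec + 1.0*E_desolv`.
#'
#' @param w_vdw,w_elec,w_desolv Component weights.
#' @return A `score_weights` list.
#' @export
score_weights <- function(w_vdw = 1.0, w_elec = 0.2, w_desolv = 1.0) {
  stopifnot(is.finite(w_vdw), is.finite(w_elec), is.finite(w_desolv))
  structure(list(w_vdw = w_vdw, w_elec = w_elec, w_desolv = w_desolv),
            class = "score_weights")
}

#' HADDOCK-style model score
#'
#' @param e_vdw,e_elec,e_desolv Component energies in kcal/mol
#'   (vectorised).
#' @param weights A [score_weights()].
#' @return Weighted-sum score in kcal/mol.
#' @export
haddock_score <- function(e_vdw, e_elec, e_desolv = 0,
                          weights = score_weights()) {
  weights$w_vdw * e_vdw + weights$w_elec * e_elec +
    weights$w_desolv * e_desolv
}

#' Rank models by score and keep the best
#'
#' @param scores Named numeric vector of model scores (lower is better).
#' @param top_k Models to keep (default 4); clamped with a warning.
#' @return Character vector of model ids, best first; ties broken by id.
#' @export
rank_models <- function(scores, top_k = 4) {
  stopifnot(length(scores) >= 1L)
  if (is.null(names(scores)))
    names(scores) <- paste0("model", seq_along(scores))
  if (top_k > length(scores)) {
    warning("top_k exceeds model count; returning all ", length(scores))
    top_k <- length(scores)
  }
  ord <- order(scores, names(scores))
  names(scores)[ord][seq_len(top_k)]
}

#' Flag residues with outlier electrostatic contributions
#'
#' Box-and-whisker outlier rule on `E_elec`: a residue is flagged when its
#' value lies strictly below `Q1 - mult*IQR` or strictly above
#' `Q3 + mult*IQR` (quartiles by linear interpolation). Values exactly on
#' a whisker are inliers.
#'
#' @param table A `residue_energy_table` with >= 4 scored residues.
#' @param whisker_iqr_mult Whisker length in IQR units (default 2).
#' @return Data.frame of flagged rows with a `bound` column; attributes
#'   `lower`, `upper`, `whisker_iqr_mult`.
#' @export
flag_electrostatic_outliers <- function(table, whisker_iqr_mult = 2) {
  x <- table$e_elec
  keep <- !is.na(x)
  if (sum(keep) < 4L) stop("need at least 4 residues with E_elec")
  q <- stats::quantile(x[keep], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - whisker_iqr_mult * iqr
  hi <- q[2] + whisker_iqr_mult * iqr
  flag <- keep & (x < lo | x > hi)
  out <- as.data.frame(table)[flag, , drop = FALSE]
  out$bound <- ifelse(out$e_elec < lo, "lower", "upper")
  rownames(out) <- NULL
  structure(out, lower = lo, upper = hi,
            whisker_iqr_mult = whisker_iqr_mult)
}

#' Ratio of two mean interaction energies
#'
#' @param meanA,meanB Mean energies (kcal/mol); `meanB` must be nonzero.
#' @return `meanA / meanB`.
#' @export
mean_energy_ratio <- function(meanA, meanB) {
  if (meanB == 0) stop("division by zero: meanB is 0")
  meanA / meanB
}
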