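#' Per-column symbol frequencies by specificity group
#'
#' Computes, for alignment column `p`: `f_a`, the column-wide symbol
#' frequencies; `f_ai`, the within-group frequencies (one column per
#' group); and `f_i`, the fraction of sequences per group. Gaps are a
#' scoring symbol in their own right. With a pseudocount, `f_a` is the
#' group-weighted marginal of `f_ai`, so the marginal identity
#' `sum_i f_i * f_ai = f_a` holds exactly for any pseudocount.
#'
#' @param grouped An `sdp_grouped`.
#' @param p 1-based column index.
#' @param pseudocount Added to every symbol count within each group
#'   (default 0).
#' @return An object of class `column_profile` with elements `p`, `f_a`,
#'   `f_ai` (symbols x groups), `f_i`, `counts_ai`, `n_i`.
#' @export
column_profile <- function(grouped, p, pseudocount = 0) {
  stopifnot(inherits(grouped, "sdp_grouped"))
  if (p < 1L || p > grouped$alignment$length)
    stop("column out of range: ", p)
  syms <- aa_alphabet()
  col <- substr(grouped$alignment$seqs, p, p)
  names(col) <- grouped$alignment$ids
  counts <- vapply(grouped$groups, function(ids)
    table(factor(col[ids], levels = syms)), numeric(length(syms)))
  counts <- matrix(counts, nrow = length(syms),
                   dimnames = list(syms, names(grouped$groups)))
  n_i <- lengths(grouped$groups)
  f_ai <- sweep(counts + pseudocount, 2,
                n_i + pseudocount * length(syms), "/")
  f_i <- n_i / sum(n_i)
  f_a <- as.vector(f_ai %*% f_i)
  names(f_a) <- syms
  structure(list(p = p, f_a = f_a, f_ai = f_ai, f_i = f_i,
                 counts_ai = counts, n_i = n_i),
            class = "column_profile")
}

#' Mutual information between amino-acid symbol and group label
#'
#' Scores how strongly a column separates the specificity groups as the
#' mutual information I = sum_i sum_a f(i) f(a|i) log( f(a|i) / f(a) ),
#' the joint being weighted by group fraction. Zero iff the per-group
#' symbol distributions are identical; natural-log (nats) scale.
#'
#' @param profile A `column_profile`.
#' @return Non-negative score in nats.
#' @export
mutual_information <- function(profile) {
  stopifnot(inherits(profile, "column_profile"))
  f_ai <- profile$f_ai
  f_a <- profile$f_a
  f_i <- profile$f_i
  total <- 0
  for (i in seq_along(f_i)) {
    nz <- f_ai[, i] > 0
    total <- total + f_i[i] *
      sum(f_ai[nz, i] * log(f_ai[nz, i] / f_a[nz]))
  }
  max(total, 0)  # clip the -1e-17-level float residue at independence
}

#' Score every column of a grouped alignment by mutual information
#'
#' @param grouped An `sdp_grouped`.
#' @param pseudocount Passed to [column_profile()].
#' @return A `score_table` data.frame (column, score) with attributes
#'   `method = "mi"` and `base = "e"`.
#' @export
mi_scores <- function(grouped, pseudocount = 0) {
  sc <- vapply(seq_len(grouped$alignment$length), function(p)
    mutual_information(column_profile(grouped, p, pseudocount)), numeric(1))
  new_score_table(sc, method = "mi", base = "e")
}

new_score_table <- function(scores, method, flag = NULL, null_summary = NULL,
                            base = NULL) {
  df <- data.frame(column = seq_along(scores), score = as.numeric(scores))
  if (!is.null(flag)) df$flag <- flag
  structure(df, class = c("score_table", "data.frame"), method = method,
            null_summary = null_summary, base = base)
}

#' Permutation-based SDP call on mutual-information scores
#'
#' Builds a null by shuffling group labels over sequences (group sizes
#' preserved) and recomputing all column MI scores per permutation; a
#' column is flagged when its observed MI exceeds the `1 - alpha` quantile
#' of the pooled null. With `alpha >= 1` every column is flagged (the
#' degenerate no-evidence-required level).
#'
#' @param grouped An `sdp_grouped` (2 or more groups).
#' @param permutations Number of label shuffles (>= 1).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed recorded in the output.
#' @param pseudocount Passed to [column_profile()].
#' @return A `score_table` with columns `column`, `score`, `flag` and a
#'   `null_summary` attribute (mean, sd, permutations, alpha, seed,
#'   threshold).
#' @export
mi_sdp_call <- function(grouped, permutations = 200, alpha = 0.05,
                        seed = 1, pseudocount = 0) {
  if (permutations < 1L) stop("permutations must be >= 1")
  obs <- mi_scores(grouped, pseudocount)
  ids <- grouped$alignment$ids
  sizes <- lengths(grouped$groups)
  null <- withr_seed(seed, {
    unlist(lapply(seq_len(permutations), function(k) {
      perm <- sample(ids)
      gs <- split(perm, rep(names(sizes), sizes))
      pg <- assign_groups(grouped$alignment, gs)
      mi_scores(pg, pseudocount)$score
    }))
  })
  thr <- stats::quantile(null, 1 - min(alpha, 1), names = FALSE, type = 7)
  flag <- if (alpha >= 1) rep(TRUE, nrow(obs)) else obs$score > thr
  new_score_table(obs$score, method = "mi", flag = flag,
                  null_summary = list(mean = mean(null), sd = stats::sd(null),
                                      permutations = permutations,
                                      alpha = alpha, seed = seed,
                                      threshold = thr),
                  base = "e")
}

# run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

hamming <- function(m, i, j) sum(m[i, ] != m[j, ])

#' Multi-RELIEF column weighting for grouped alignments
#'
#' RELIEF-style feature weighting over alignment columns. Weights start at
#' zero; at each pick a sequence is drawn, its nearest neighbour in the
#' same group (hit) and in the opposite group (miss) are found by Hamming
#' distance (ties broken uniformly at random), and every column `i` is
#' updated by `diff/m` terms, where `diff(a,b)` is 0 when the letters
#' agree and 1 otherwise and `m` is the number of picks. Under the
#' `standard` convention the weight increases when the miss differs and
#' decreases when the hit differs, so higher weight means more
#' group-separating; `as_printed` flips the two signs. With Hamming diff
#' in \{0,1\} every weight stays in \[-1, 1\].
#'
#' With more than two groups each group is scored against the pooled rest
#' and the per-column weights are averaged over groups.
#'
#' @param grouped An `sdp_grouped`; every group needs >= 2 sequences.
#' @param m Number of picks; default one pick per sequence.
#' @param sampling `"each_once"` (default; every sequence picked exactly
#'   once, order-independent up to tie-breaking) or `"random"` (uniform
#'   with replacement).
#' @param seed Integer seed (tie-breaks and random sampling).
#' @param sign_convention `"standard"` (default) or `"as_printed"`.
#' @return An object of class `relief_state`: list with `w` (per-column
#'   weight), `m`, `sampling`, `sign_convention`, `seed`, `log`
#'   (per-pick data.frame of sequence/hit/miss ids).
#' @export
multi_relief <- function(grouped, m = NULL,
                         sampling = c("each_once", "random"), seed = 1,
                         sign_convention = c("standard", "as_printed")) {
  sampling <- match.arg(sampling)
  sign_convention <- match.arg(sign_convention)
  small <- names(grouped$groups)[lengths(grouped$groups) < 2L]
  if (length(small) > 0L)
    stop("degenerate group(s) with a single sequence (no hit exists): ",
         paste(small, collapse = ", "))
  res <- withr_seed(seed, {
    if (grouped$N == 2L) {
      relief_two_group(grouped, m, sampling, sign_convention)
    } else {
      runs <- lapply(names(grouped$groups), function(g) {
        rest <- setdiff(names(grouped$groups), g)
        spec <- list(unlist(grouped$groups[g], use.names = FALSE),
                     unlist(grouped$groups[rest], use.names = FALSE))
        names(spec) <- c(g, "rest")
        relief_two_group(assign_groups(grouped$alignment, spec),
                         m, sampling, sign_convention)
      })
      w <- rowMeans(vapply(runs, `[[`, numeric(grouped$alignment$length), "w"))
      list(w = w, m = runs[[1]]$m, log = do.call(rbind, lapply(runs, `[[`, "log")))
    }
  })
  structure(list(w = res$w, m = res$m, sampling = sampling,
                 sign_convention = sign_convention, seed = seed,
                 log = res$log),
            class = "relief_state")
}

relief_two_group <- function(grouped, m, sampling, sign_convention) {
  mat <- alignment_matrix(grouped$alignment)
  ids <- grouped$alignment$ids
  grp <- character(length(ids))
  names(grp) <- ids
  for (g in names(grouped$groups)) grp[grouped$groups[[g]]] <- g
  grp <- grp[ids]
  n <- length(ids)
  if (is.null(m)) m <- if (sampling == "each_once") n else n
  picks <- if (sampling == "each_once") {
    if (m != n)
      warning("each_once sampling uses one pick per sequence; m set to ", n)
    seq_len(n)
  } else {
    sample.int(n, m, replace = TRUE)
  }
  m_eff <- length(picks)
  w <- numeric(ncol(mat))
  log <- data.frame(pick = seq_len(m_eff), seq = ids[picks],
                    hit = NA_character_, miss = NA_character_)
  sgn <- if (sign_convention == "standard") c(hit = -1, miss = +1)
         else c(hit = +1, miss = -1)
  for (k in seq_len(m_eff)) {
    s <- picks[k]
    same <- setdiff(which(grp == grp[s]), s)
    other <- which(grp != grp[s])
    dsame <- vapply(same, function(j) hamming(mat, s, j), numeric(1))
    dother <- vapply(other, function(j) hamming(mat, s, j), numeric(1))
    hit <- same[pick_min(dsame)]
    miss <- other[pick_min(dother)]
    dh <- (mat[s, ] != mat[hit, ]) * 1
    dm <- (mat[s, ] != mat[miss, ]) * 1
    w <- w + (sgn["miss"] * dm + sgn["hit"] * dh) / m_eff
    log$hit[k] <- ids[hit]
    log$miss[k] <- ids[miss]
  }
  names(w) <- seq_len(ncol(mat))
  list(w = w, m = m_eff, log = log)
}

# index of the minimum, ties broken uniformly at random
pick_min <- function(d) {
  idx <- which(d == min(d))
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

#' Multi-RELIEF scores as a score table
#'
#' @param grouped An `sdp_grouped`.
#' @param ... Passed to [multi_relief()].
#' @return A `score_table` (column, score) with `method = "multirelief"`.
#' @export
multirelief_scores <- function(grouped, ...) {
  st <- multi_relief(grouped, ...)
  new_score_table(st$w, method = "multirelief")
}

#' Sequence-harmony score of a two-group column
#'
#' A symmetrised relative-entropy (Jensen-Shannon-style) divergence between
#' the two within-group symbol distributions, mapped to \[0, 1\] as
#' `1 - divergence`: 1 means identical distributions (full harmony), 0
#' means disjoint symbol supports (maximal group separation). Low harmony
#' marks SDP candidates.
#'
#' @param profile A `column_profile` built from exactly 2 groups.
#' @param pseudocount Re-applied to the stored per-group counts
#'   (default 0).
#' @return Score in \[0, 1\].
#' @export
sequence_harmony <- function(profile, pseudocount = 0) {
  stopifnot(inherits(profile, "column_profile"))
  if (length(profile$f_i) != 2L)
    stop("sequence harmony requires exactly 2 groups, got ",
         length(profile$f_i))
  K <- nrow(profile$counts_ai)
  pA <- (profile$counts_ai[, 1] + pseudocount) /
    (profile$n_i[1] + pseudocount * K)
  pB <- (profile$counts_ai[, 2] + pseudocount) /
    (profile$n_i[2] + pseudocount * K)
  term <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * log2(2 * p[nz] / (p[nz] + q[nz])))
  }
  val <- (term(pA, pB) + term(pB, pA)) / 2
  1 - min(max(val, 0), 1)
}

#' Sequence-harmony scores for every column
#'
#' @param grouped An `sdp_grouped` with exactly 2 groups.
#' @param pseudocount Passed to [sequence_harmony()].
#' @return A `score_table` with `method = "harmony"` (low = SDP-like).
#' @export
harmony_scores <- function(grouped, pseudocount = 0) {
  sc <- vapply(seq_len(grouped$alignment$length), function(p)
    sequence_harmony(column_profile(grouped, p), pseudocount), numeric(1))
  new_score_table(sc, method = "harmony")
}

#' Rank columns and select SDP candidates from a score table
#'
#' MI and Multi-RELIEF select high scores; harmony selects low scores.
#' Ordering is stable with ties broken by lower column index.
#'
#' @param scores A `score_table`.
#' @param top_k Number of top columns to return (clamped to the column
#'   count with a warning).
#' @param threshold Alternative to `top_k`: keep columns with score
#'   `>= threshold` (high-select methods) or `<= threshold` (harmony).
#' @return Integer vector of selected column indices, best first.
#' @export
rank_and_select <- function(scores, top_k = NULL, threshold = NULL) {
  method <- attr(scores, "method")
  dir_low <- identical(method, "harmony")
  key <- if (dir_low) scores$score else -scores$score
  ord <- order(key, scores$column)
  if (!is.null(threshold)) {
    keep <- if (dir_low) scores$score <= threshold else scores$score >= threshold
    return(scores$column[ord][keep[ord]])
  }
  if (is.null(top_k)) stop("supply top_k or threshold")
  if (top_k > nrow(scores)) {
    warning("top_k exceeds column count; clamped to ", nrow(scores))
    top_k <- nrow(scores)
  }
  scores$column[ord][seq_len(top_k)]
}

#' Score columns with one or all sequence-stage methods
#'
#' Convenience front end over [mi_sdp_call()], [multirelief_scores()] and
#' [harmony_scores()], optionally annotating reference numbering.
#'
#' @param grouped An `sdp_grouped`.
#' @param method One of `"mi"`, `"multirelief"`, `"harmony"`, `"all"`.
#' @param reference_id Optional reference record id; adds a
#'   `reference_position` column via [map_columns_to_reference()].
#' @param permutations,alpha,seed,pseudocount Method parameters.
#' @return A single `score_table`, or a named list of them for `"all"`.
#' @export
score_columns <- function(grouped,
                          method = c("mi", "multirelief", "harmony", "all"),
                          reference_id = NULL, permutations = 200,
                          alpha = 0.05, seed = 1, pseudocount = 0) {
  method <- match.arg(method)
  annotate <- function(st) {
    if (!is.null(reference_id)) {
      pm <- map_columns_to_reference(grouped, reference_id)
      st$reference_position <- unclass(pm)[as.character(st$column)]
    }
    st
  }
  run <- function(mth) switch(mth,
    mi = mi_sdp_call(grouped, permutations, alpha, seed, pseudocount),
    multirelief = multirelief_scores(grouped, seed = seed),
    harmony = harmony_scores(grouped, pseudocount))
  if (method == "all") {
    lapply(stats::setNames(nm = c("mi", "multirelief", "harmony")),
           function(m) annotate(run(m)))
  } else {
    annotate(run(method))
  }
}
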