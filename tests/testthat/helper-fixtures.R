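# Small in-code fixtures shared across the suite.

# 2x2 grouped alignment: columns 4-5 fully separate the groups.
tiny_grouped <- function() {
  aln <- as_alignment(c("a1", "a2", "b1", "b2"),
                      c("ACDEE", "ACDEE", "ACDQQ", "ACDQQ"))
  assign_groups(aln, list(g1 = c("a1", "a2"), g2 = c("b1", "b2")))
}

# random grouped alignment (uniform letters), n per group, L columns
random_grouped <- function(n_groups = 2, n_per_group = 4, L = 10,
                           alphabet = c("A", "C", "D", "E")) {
  ids <- paste0("s", seq_len(n_groups * n_per_group))
  seqs <- vapply(ids, function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
  grp <- split(ids, rep(paste0("g", seq_len(n_groups)), each = n_per_group))
  assign_groups(as_alignment(ids, seqs), grp)
}

# independent brute-force mutual information from raw per-group counts
mi_bruteforce <- function(profile) {
  counts <- profile$counts_ai
  n <- sum(counts)
  total <- 0
  for (i in seq_len(ncol(counts))) {
    for (a in seq_len(nrow(counts))) {
      p_ai <- counts[a, i] / n                  # joint
      if (p_ai == 0) next
      p_a <- sum(counts[a, ]) / n               # symbol marginal
      p_i <- sum(counts[, i]) / n               # group marginal
      total <- total + p_ai * log(p_ai / (p_a * p_i))
    }
  }
  total
}

# frame with explicit atoms; spec rows: chain, resno, resid, elety, element, x, y, z
frame_from_atoms <- function(..., sides = c(A = "receptor", B = "ligand")) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r[[1]], resno = as.integer(r[[2]]), ins = "",
               resid = r[[3]], elety = r[[4]], element = r[[5]],
               x = as.numeric(r[[6]]), y = as.numeric(r[[7]]),
               z = as.numeric(r[[8]]), stringsAsFactors = FALSE)))
  sdp_frame(atoms, sides)
}

# two opposite-charge atoms (Glu OE1 / Lys NZ) across the interface at distance d
saltbridge_frame <- function(d) {
  frame_from_atoms(
    list("A", 1, "GLU", "OE1", "O", 0, 0, 0),
    list("B", 1, "LYS", "NZ", "N", d, 0, 0))
}

random_rigid_transform <- function(xyz) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), nrow = 3, byrow = TRUE)
  t(R %*% t(xyz)) + matrix(stats::rnorm(3, sd = 5), nrow(xyz), 3,
                           byrow = TRUE)
}

apply_rigid <- function(frame) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  xyz <- random_rigid_transform(xyz)
  frame$atoms$x <- xyz[, 1]; frame$atoms$y <- xyz[, 2]
  frame$atoms$z <- xyz[, 3]
  frame
}
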