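# Small in-code fixtures and independent oracles shared across tests.

# A three-gene registry: one single-copy triad, one two-copy triad, and
# one triad with an unplaced locus that needs an override.
tiny_registry_table <- function() {
  data.frame(
    gene_name = c("GeneOne", "GeneOne", "GeneOne",
                  "GeneTwo", "GeneTwo", "GeneTwo", "GeneTwo",
                  "GeneTwo", "GeneTwo",
                  "GeneUn", "GeneUn", "GeneUn"),
    gene_id = c("TraesCS1A02G100000", "TraesCS1B02G100100",
                "TraesCS1D02G100200",
                "TraesCS2A02G200000", "TraesCS2A02G200100",
                "TraesCS2B02G200200", "TraesCS2B02G200300",
                "TraesCS2D02G200400", "TraesCS2D02G200500",
                "TraesCS3A02G300000", "TraesCS3B02G300100",
                "TraesCSU02G300200"),
    stringsAsFactors = FALSE
  )
}

tiny_registry <- function() {
  load_registry(tiny_registry_table(),
                overrides = c(TraesCSU02G300200 = "D"))
}

# Dense expression matrix over a registry: constant tpm per locus across
# samples (so means are exact), values supplied as a named vector.
constant_matrix <- function(locus_tpm, samples = c("s1", "s2"),
                            condition = "control") {
  records <- expand.grid(locus_raw_id = names(locus_tpm),
                         sample_id = samples,
                         stringsAsFactors = FALSE)
  records$tpm <- locus_tpm[records$locus_raw_id]
  meta <- data.frame(sample_id = samples, study = "study1",
                     tissue = "leaf", condition = condition,
                     stringsAsFactors = FALSE)
  expression_matrix(records, meta)
}

# Independent nearest-centroid oracle: centroid coordinates written out
# by hand, distances by explicit arithmetic (no package geometry code).
oracle_distances <- function(f) {
  cen <- list(balanced = c(1 / 3, 1 / 3, 1 / 3),
              A_dominant = c(1, 0, 0),
              B_dominant = c(0, 1, 0),
              D_dominant = c(0, 0, 1),
              A_suppressed = c(0, 0.5, 0.5),
              B_suppressed = c(0.5, 0, 0.5),
              D_suppressed = c(0.5, 0.5, 0))
  vapply(cen, function(cc)
    sqrt((f[1] - cc[1])^2 + (f[2] - cc[2])^2 + (f[3] - cc[3])^2),
    numeric(1))
}

# Score one explicit (gapped) alignment under the affine convention:
# substitution score per residue column, each gap run costs
# gap_open + run_length * gap_extend.
score_gapped_pair <- function(ga, gb, match, mismatch, gap_open, gap_extend) {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  s <- 0
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-")
      s <- s + if (a[k] == b[k]) match else mismatch
  }
  gap_run_cost <- function(x) {
    r <- rle(x == "-")
    sum(ifelse(r$values, gap_open + r$lengths * gap_extend, 0))
  }
  s + gap_run_cost(a) + gap_run_cost(b)
}

# Exhaustive enumeration of every global alignment of two short strings
# (no gap-gap columns), returning the optimal score. Independent of any
# dynamic program.
enumerate_best_score <- function(sa, sb, match, mismatch,
                                 gap_open, gap_extend) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, ga, gb) {
    if (i > length(a) && j > length(b)) {
      sc <- score_gapped_pair(paste(ga, collapse = ""),
                              paste(gb, collapse = ""),
                              match, mismatch, gap_open, gap_extend)
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recurse(i + 1, j + 1, c(ga, a[i]), c(gb, b[j]))
    if (i <= length(a))
      recurse(i + 1, j, c(ga, a[i]), c(gb, "-"))
    if (j <= length(b))
      recurse(i, j + 1, c(ga, "-"), c(gb, b[j]))
  }
  recurse(1, 1, character(), character())
  best
}

# Independent Gotoh-style affine dynamic program (iterative), used as
# the oracle for the exhaustive small-sequence sweep. Gap of length L
# costs gap_open + L * gap_extend.
gotoh_best_score <- function(sa, sb, match, mismatch,
                             gap_open, gap_extend) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)  # last column is residue-residue
  X <- matrix(NEG, n + 1, m + 1)  # last column consumes a (gap in b)
  Y <- matrix(NEG, n + 1, m + 1)  # last column consumes b (gap in a)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend,
                             Y[i, j + 1] + gap_open + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend,
                             X[i + 1, j] + gap_open + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Random point on the 2-simplex (uniform via normalised exponentials).
random_simplex <- function(n) {
  x <- matrix(stats::rexp(3 * n), n, 3)
  x / rowSums(x)
}
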