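# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards so simulations never perturb user RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a synthetic triad-expression dataset
#'
#' Describes the generative model behind [simulate_dataset()]: a set of
#' genes, each with a fixed number of loci per subgenome (so multi-copy
#' genes like the RbcS tandem family, 9/8/8 copies on A/B/D, can be
#' emulated), a true subgenome fraction triple, and a baseline total
#' expression in tpm; a list of contexts each sampled \code{n_samples}
#' times; multiplicative log-normal per-(locus, sample) noise of mean 1
#' parameterised by its coefficient of variation; and optional stress
#' effects that multiply specific homoeologs' expression in a specific
#' context (emulating, e.g., preferential heat induction of a D
#' homoeolog).
#'
#' @param genes Data frame with columns \code{gene_name},
#'   \code{loci_A}, \code{loci_B}, \code{loci_D} (positive integers),
#'   \code{frac_A}, \code{frac_B}, \code{frac_D} (true fractions,
#'   summing to 1), \code{base_tpm} (positive baseline total).
#' @param n_samples Samples per context (positive integer).
#' @param contexts Character vector of context names (become the
#'   \code{condition} metadata field).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise; 0 gives noise-free data.
#' @param stress_effects Optional data frame with columns
#'   \code{gene_name}, \code{subgenome}, \code{multiplier} (> 0) and
#'   \code{context}; each row multiplies that homoeolog's expression in
#'   that context only.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(genes, n_samples = 10L,
                            contexts = "control", noise_cv = 0,
                            stress_effects = NULL, seed = 1L) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  need <- c("gene_name", "loci_A", "loci_B", "loci_D",
            "frac_A", "frac_B", "frac_D", "base_tpm")
  if (!all(need %in% names(genes)))
    stop("genes must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_name)) stop("duplicate gene_name in genes")
  loci <- as.matrix(genes[c("loci_A", "loci_B", "loci_D")])
  if (any(loci < 1) || any(loci != round(loci)))
    stop("loci counts must be positive integers")
  fr <- as.matrix(genes[c("frac_A", "frac_B", "frac_D")])
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-9))
    stop("true fractions must be non-negative and sum to 1 per gene")
  if (any(genes$base_tpm <= 0)) stop("base_tpm must be positive")
  stopifnot(n_samples >= 1L, noise_cv >= 0, length(contexts) >= 1L)
  if (anyDuplicated(contexts)) stop("duplicate context names")
  if (!is.null(stress_effects)) {
    stress_effects <- as.data.frame(stress_effects, stringsAsFactors = FALSE)
    need_s <- c("gene_name", "subgenome", "multiplier", "context")
    if (!all(need_s %in% names(stress_effects)))
      stop("stress_effects must have columns ", paste(need_s, collapse = ", "))
    if (!all(stress_effects$gene_name %in% genes$gene_name))
      stop("stress_effects refers to unknown gene(s)")
    if (!all(stress_effects$subgenome %in% c("A", "B", "D")))
      stop("stress_effects subgenome must be A, B or D")
    if (any(stress_effects$multiplier <= 0))
      stop("stress multipliers must be positive")
    if (!all(stress_effects$context %in% contexts))
      stop("stress_effects refers to unknown context(s)")
  }
  structure(list(genes = genes, n_samples = as.integer(n_samples),
                 contexts = contexts, noise_cv = noise_cv,
                 stress_effects = stress_effects, seed = as.integer(seed)),
            class = "simulation_spec")
}

stress_multiplier <- function(spec, gene, subgenome, context) {
  se <- spec$stress_effects
  if (is.null(se)) return(1)
  hit <- se$gene_name == gene & se$subgenome == subgenome &
    se$context == context
  if (any(hit)) prod(se$multiplier[hit]) else 1
}

#' Simulate a registry, expression matrix and truth table
#'
#' Realises a [simulation_spec()]: every gene gets well-formed synthetic
#' wheat-style Gene_IDs (one per locus, valid under [parse_gene_id()]);
#' each (locus, sample) tpm is
#' \code{base_tpm * frac / n_copies * stress_multiplier * noise}, with
#' the subgenome's share split equally across its copies and noise drawn
#' log-normal with mean 1 and CV \code{noise_cv}. The truth table
#' records, per gene and context, the expected fractions implied by the
#' true fractions and stress multipliers (the noise has mean 1, so these
#' are the noise-free values), the expected balance category, and - for
#' every ordered context pair - whether the category changes. Output is
#' fully reproducible from the spec's seed.
#'
#' @param spec A \code{simulation_spec}.
#' @return List with \code{registry_table} (data frame: gene_name,
#'   gene_id), \code{registry} (loaded \code{triad_registry}),
#'   \code{expression} (an [expression_matrix()]), and \code{truth}
#'   (list with \code{balance}: per gene x context expected fractions
#'   and category; \code{shifts}: per gene x ordered context pair
#'   expected \code{changed} flag).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  genes <- spec$genes
  subs <- c("A", "B", "D")

  # registry with synthetic but well-formed IDs
  reg_rows <- list()
  counter <- 0L
  for (i in seq_len(nrow(genes))) {
    chrom <- (i - 1L) %% 7L + 1L
    for (s in subs) {
      n_cop <- genes[[paste0("loci_", s)]][i]
      for (k in seq_len(n_cop)) {
        counter <- counter + 1L
        reg_rows[[counter]] <- data.frame(
          gene_name = genes$gene_name[i],
          gene_id = sprintf("TraesCS%d%s02G%06d", chrom, s, counter * 100L),
          subgenome = s, gene_index = i,
          stringsAsFactors = FALSE)
      }
    }
  }
  reg_tab <- do.call(rbind, reg_rows)
  registry <- load_registry(reg_tab[c("gene_name", "gene_id")])

  n_ctx <- length(spec$contexts)
  sample_ids <- unlist(lapply(spec$contexts, function(cx)
    sprintf("%s_s%02d", cx, seq_len(spec$n_samples))))
  meta <- data.frame(
    sample_id = sample_ids,
    study = "synthetic_study",
    tissue = "seedling",
    condition = rep(spec$contexts, each = spec$n_samples),
    stringsAsFactors = FALSE)

  # per-locus per-context noise-free tpm
  base_locus <- numeric(nrow(reg_tab))
  for (r in seq_len(nrow(reg_tab))) {
    i <- reg_tab$gene_index[r]
    s <- reg_tab$subgenome[r]
    base_locus[r] <- genes$base_tpm[i] * genes[[paste0("frac_", s)]][i] /
      genes[[paste0("loci_", s)]][i]
  }

  records <- with_seed(spec$seed, {
    recs <- vector("list", n_ctx)
    if (spec$noise_cv > 0) {
      sigma2 <- log(1 + spec$noise_cv^2)
      meanlog <- -sigma2 / 2
    }
    for (ci in seq_len(n_ctx)) {
      cx <- spec$contexts[ci]
      mult <- vapply(seq_len(nrow(reg_tab)), function(r)
        stress_multiplier(spec, reg_tab$gene_name[r], reg_tab$subgenome[r], cx),
        numeric(1))
      ids_cx <- meta$sample_id[meta$condition == cx]
      n_cells <- nrow(reg_tab) * length(ids_cx)
      noise <- if (spec$noise_cv > 0)
        stats::rlnorm(n_cells, meanlog, sqrt(sigma2)) else rep(1, n_cells)
      recs[[ci]] <- data.frame(
        locus_raw_id = rep(reg_tab$gene_id, times = length(ids_cx)),
        sample_id = rep(ids_cx, each = nrow(reg_tab)),
        tpm = rep(base_locus * mult, times = length(ids_cx)) * noise,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, recs)
  })
  expr <- expression_matrix(records, meta, dense = TRUE)

  # truth: expected fractions and category per (gene, context)
  bal_rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (cx in spec$contexts) {
      tot <- vapply(subs, function(s)
        genes$base_tpm[i] * genes[[paste0("frac_", s)]][i] *
          stress_multiplier(spec, genes$gene_name[i], s, cx), numeric(1))
      fr <- tot / sum(tot)
      bal_rows[[length(bal_rows) + 1L]] <- data.frame(
        gene_name = genes$gene_name[i], context = cx,
        frac_A = fr[["A"]], frac_B = fr[["B"]], frac_D = fr[["D"]],
        total = sum(tot),
        category = classify_balance(fr)$category,
        stringsAsFactors = FALSE)
    }
  }
  balance <- do.call(rbind, bal_rows)

  shift_rows <- list()
  if (n_ctx >= 2L) {
    for (i in seq_len(nrow(genes))) for (c1 in spec$contexts)
      for (c2 in setdiff(spec$contexts, c1)) {
        b1 <- balance[balance$gene_name == genes$gene_name[i] &
                        balance$context == c1, ]
        b2 <- balance[balance$gene_name == genes$gene_name[i] &
                        balance$context == c2, ]
        shift_rows[[length(shift_rows) + 1L]] <- data.frame(
          gene_name = genes$gene_name[i],
          context_from = c1, context_to = c2,
          changed = b1$category != b2$category,
          stringsAsFactors = FALSE)
      }
  }
  shifts <- if (length(shift_rows)) do.call(rbind, shift_rows) else
    data.frame(gene_name = character(), context_from = character(),
               context_to = character(), changed = logical())

  list(registry_table = reg_tab[c("gene_name", "gene_id")],
       registry = registry,
       expression = expr,
       truth = list(balance = balance, shifts = shifts))
}

#' Simulate near-identical homoeolog sequences with known substitutions
#'
#' Generates an A/B/D homoeolog trio from one random base sequence, with
#' exactly the requested number of differences between each pair and all
#' substitutions at distinct positions. Each substituted position
#' diverges in exactly one subgenome, so the pairwise counts must be
#' consistent: with a, b, d positions diverging only in A, B, D
#' respectively, the pair counts are AB = a + b, AD = a + d,
#' BD = b + d; the requested triple is solved for (a, b, d) and rejected
#' if any solution component is negative or fractional. This mirrors the
#' structure seen in real homoeolog trios where, e.g., A and D copies
#' are identical while B carries a few private substitutions.
#'
#' @param base_length Sequence length (positive integer).
#' @param substitutions Named numeric vector
#'   \code{c(AB = , AD = , BD = )} of pairwise difference counts.
#' @param alphabet \code{"protein"} (20 standard amino acids) or
#'   \code{"nucleotide"} (ACGT).
#' @param seed Integer seed.
#' @return List with \code{sequences} (named character vector A, B, D)
#'   and \code{truth} (data frame: \code{position},
#'   \code{diverged_subgenome}, \code{residue_base},
#'   \code{residue_new}, ordered by position).
#' @examples
#' sim <- simulate_homoeolog_sequences(380, c(AB = 4, AD = 0, BD = 4),
#'                                     seed = 7)
#' mean_pairwise_identity(sim$sequences)
#' @export
simulate_homoeolog_sequences <- function(base_length,
                                         substitutions = c(AB = 4, AD = 0,
                                                           BD = 4),
                                         alphabet = c("protein",
                                                      "nucleotide"),
                                         seed = 1L) {
  alphabet <- match.arg(alphabet)
  stopifnot(base_length >= 1L, base_length == round(base_length))
  need <- c("AB", "AD", "BD")
  if (!all(need %in% names(substitutions)))
    stop("substitutions must be named c(AB = , AD = , BD = )")
  ab <- substitutions[["AB"]]; ad <- substitutions[["AD"]]
  bd <- substitutions[["BD"]]
  a_only <- (ab + ad - bd) / 2
  b_only <- (ab + bd - ad) / 2
  d_only <- (ad + bd - ab) / 2
  counts <- c(A = a_only, B = b_only, D = d_only)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("inconsistent pairwise substitution counts: no single-divergence ",
         "assignment solves AB=", ab, ", AD=", ad, ", BD=", bd)
  n_sub <- sum(counts)
  if (n_sub > base_length)
    stop("total substitutions (", n_sub, ") exceed base_length (",
         base_length, ")")
  letters_pool <- if (alphabet == "protein")
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] else c("A", "C", "G", "T")

  with_seed(seed, {
    base <- sample(letters_pool, base_length, replace = TRUE)
    seqs <- list(A = base, B = base, D = base)
    truth <- data.frame(position = integer(), diverged_subgenome = character(),
                        residue_base = character(), residue_new = character(),
                        stringsAsFactors = FALSE)
    if (n_sub > 0) {
      pos <- sample.int(base_length, n_sub)
      who <- rep(names(counts), times = counts)
      new_res <- vapply(seq_len(n_sub), function(k)
        sample(setdiff(letters_pool, base[pos[k]]), 1L), character(1))
      for (k in seq_len(n_sub)) seqs[[who[k]]][pos[k]] <- new_res[k]
      truth <- data.frame(position = pos, diverged_subgenome = who,
                          residue_base = base[pos], residue_new = new_res,
                          stringsAsFactors = FALSE)
      truth <- truth[order(truth$position), ]
      rownames(truth) <- NULL
    }
    list(sequences = vapply(seqs, paste, character(1), collapse = ""),
         truth = truth)
  })
}

#' Write a simulated dataset to plain-text fixture files
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(registry = file.path(dir, "registry.tsv"),
             expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"))
  utils::write.table(dataset$registry_table, paths["registry"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- dataset$expression$records
  names(expr)[names(expr) == "locus_raw_id"] <- "gene_id"
  utils::write.table(expr, paths["expression"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$expression$sample_meta, paths["samples"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$balance, paths["truth"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
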