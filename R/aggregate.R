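#' Construct a tpm expression matrix
#'
#' Bundles long-format expression records (one row per locus per sample,
#' values in transcripts per million) with per-sample metadata. tpm is a
#' within-sample normalised unit, so records are never renormalised
#' here; the object is a validated container.
#'
#' @param records Data frame with columns \code{locus_raw_id},
#'   \code{sample_id}, \code{tpm}.
#' @param sample_meta Data frame with columns \code{sample_id},
#'   \code{study}, \code{tissue}, \code{condition}; one row per sample.
#' @param dense If \code{TRUE} (default) the records are declared
#'   complete: a locus missing from a selected sample at aggregation
#'   time is an error, because silent zero-filling hides mismatches
#'   between registry and expression table. If \code{FALSE}, missing
#'   cells take the value \code{fill}.
#' @param fill Value for missing cells when \code{dense = FALSE}.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(records, sample_meta, dense = TRUE, fill = 0) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  need_r <- c("locus_raw_id", "sample_id", "tpm")
  need_m <- c("sample_id", "study", "tissue", "condition")
  if (!all(need_r %in% names(records)))
    stop("records must have columns ", paste(need_r, collapse = ", "))
  if (!all(need_m %in% names(sample_meta)))
    stop("sample_meta must have columns ", paste(need_m, collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample_id in sample_meta")
  if (nrow(records)) {
    if (any(is.na(records$tpm)) || any(records$tpm < 0))
      stop("tpm values must be non-negative and non-missing")
    key <- paste(records$locus_raw_id, records$sample_id, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (locus, sample) pair in records: ",
           paste(utils::head(unique(sub("\r", " / ", key[duplicated(key)])), 5L),
                 collapse = "; "))
    orphan <- setdiff(unique(records$sample_id), sample_meta$sample_id)
    if (length(orphan))
      stop("samples present in records but missing metadata: ",
           paste(orphan, collapse = ", "))
  }
  structure(list(records = records[need_r],
                 sample_meta = sample_meta[need_m],
                 dense = isTRUE(dense),
                 fill = fill),
            class = "expression_matrix")
}

#' Read an expression matrix from TSV files
#'
#' Long format: an expression TSV with columns
#' \code{gene_id}, \code{sample_id}, \code{tpm} and a metadata TSV with
#' columns \code{sample_id}, \code{study}, \code{tissue},
#' \code{condition}.
#'
#' @param expression_tsv Path to the long-format expression TSV.
#' @param meta_tsv Path to the sample-metadata TSV.
#' @inheritParams expression_matrix
#' @return An \code{expression_matrix}.
#' @export
read_expression <- function(expression_tsv, meta_tsv, dense = TRUE, fill = 0) {
  expr <- utils::read.delim(expression_tsv, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "sample_id", "tpm") %in% names(expr)))
    stop("expression TSV must have columns gene_id, sample_id, tpm")
  meta <- utils::read.delim(meta_tsv, stringsAsFactors = FALSE,
                            colClasses = "character")
  names(expr)[names(expr) == "gene_id"] <- "locus_raw_id"
  expression_matrix(expr, meta, dense = dense, fill = fill)
}

#' Read a wide (loci x samples) expression CSV
#'
#' First column \code{gene_id}, remaining columns one per sample. A wide
#' matrix is dense by construction.
#'
#' @param expression_csv Path to the wide CSV.
#' @param meta_tsv Path to the sample-metadata TSV.
#' @return An \code{expression_matrix} with \code{dense = TRUE}.
#' @export
read_expression_wide <- function(expression_csv, meta_tsv) {
  wide <- utils::read.csv(expression_csv, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(wide)[1] != "gene_id")
    stop("wide expression CSV must have first column gene_id")
  samples <- names(wide)[-1]
  long <- data.frame(
    locus_raw_id = rep(wide$gene_id, times = length(samples)),
    sample_id = rep(samples, each = nrow(wide)),
    tpm = as.numeric(unlist(wide[-1], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  meta <- utils::read.delim(meta_tsv, stringsAsFactors = FALSE,
                            colClasses = "character")
  expression_matrix(long, meta, dense = TRUE)
}

# Resolve a context filter (named list of metadata equalities, or a
# predicate on the sample_meta data frame) to a vector of sample_ids.
select_samples <- function(matrix, sample_filter) {
  meta <- matrix$sample_meta
  if (is.function(sample_filter)) {
    keep <- sample_filter(meta)
    if (!is.logical(keep) || length(keep) != nrow(meta))
      stop("a predicate sample_filter must return one logical per sample")
  } else if (is.list(sample_filter)) {
    fields <- names(sample_filter)
    bad <- setdiff(fields, c("study", "tissue", "condition"))
    if (length(bad))
      stop("unknown sample metadata field(s): ", paste(bad, collapse = ", "))
    keep <- rep(TRUE, nrow(meta))
    for (f in fields) keep <- keep & meta[[f]] %in% sample_filter[[f]]
  } else {
    stop("sample_filter must be a named list of metadata values or a predicate function")
  }
  meta$sample_id[keep]
}

#' Mean tpm per locus over a set of samples
#'
#' Computes, for every locus in the matrix, the arithmetic mean tpm over
#' the samples passing the filter, pooling samples across studies with
#' equal weight (see \code{stratify_by_study} for the per-study
#' alternative).
#'
#' @param matrix An \code{expression_matrix}.
#' @param sample_filter A named list of metadata equalities (e.g.
#'   \code{list(tissue = "leaf", condition = "control")}; values may be
#'   vectors, matched with \code{\%in\%}) or a predicate function taking
#'   the sample-metadata data frame and returning a logical per sample.
#' @param stratify_by_study If \code{TRUE}, compute per-study means
#'   first and average those, giving every study equal weight regardless
#'   of its sample count. Default \code{FALSE}: one pooled mean with
#'   equal per-sample weight.
#' @return Named numeric vector, locus id -> mean tpm.
#' @export
mean_tpm_per_locus <- function(matrix, sample_filter,
                               stratify_by_study = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"))
  ids <- select_samples(matrix, sample_filter)
  if (length(ids) == 0L)
    stop("sample filter matched no samples")
  loci <- unique(matrix$records$locus_raw_id)
  rec <- matrix$records[matrix$records$sample_id %in% ids, ]

  cell_means <- function(rec_sub, ids_sub) {
    # mean over ids_sub for each locus, honouring the dense/fill contract
    n_present <- table(factor(rec_sub$locus_raw_id, levels = loci))
    if (matrix$dense) {
      short <- names(n_present)[n_present < length(ids_sub)]
      if (length(short))
        stop("dense matrix is missing (locus, sample) cells for: ",
             paste(short, collapse = ", "))
      sums <- tapply(rec_sub$tpm, factor(rec_sub$locus_raw_id, levels = loci),
                     sum, default = 0)
      sums / length(ids_sub)
    } else {
      sums <- tapply(rec_sub$tpm, factor(rec_sub$locus_raw_id, levels = loci),
                     sum, default = 0)
      n_missing <- length(ids_sub) - as.numeric(n_present)
      (sums + n_missing * matrix$fill) / length(ids_sub)
    }
  }

  if (!stratify_by_study) {
    out <- cell_means(rec, ids)
  } else {
    meta <- matrix$sample_meta
    studies <- unique(meta$study[meta$sample_id %in% ids])
    per_study <- vapply(studies, function(st) {
      ids_st <- intersect(ids, meta$sample_id[meta$study == st])
      cell_means(rec[rec$sample_id %in% ids_st, ], ids_st)
    }, numeric(length(loci)))
    if (!is.matrix(per_study))          # single locus: one value per study
      per_study <- matrix(per_study, nrow = length(loci))
    out <- rowMeans(per_study)
  }
  stats::setNames(as.numeric(out), loci)
}

#' Per-subgenome total expression of one gene
#'
#' Sums mean tpm over the gene's loci within each subgenome (using the
#' registry's effective subgenome assignments), the aggregation that
#' collapses multi-copy genes such as RbcS to a single A/B/D triple:
#' e.g. total A expression of Cpn60 is the sum of the mean tpm of its
#' two A-subgenome loci.
#'
#' @param mean_tpm Named numeric vector from [mean_tpm_per_locus()].
#' @param registry A \code{triad_registry}.
#' @param gene_name Gene to aggregate.
#' @return Named numeric vector \code{c(A = , B = , D = )} of total tpm.
#' @export
subgenome_totals <- function(mean_tpm, registry, gene_name) {
  stopifnot(inherits(registry, "triad_registry"))
  sub <- registry[registry$gene_name == gene_name, ]
  if (nrow(sub) == 0L) stop("unknown gene name: ", gene_name)
  missing_ids <- setdiff(sub$raw_id, names(mean_tpm))
  if (length(missing_ids))
    stop("loci of '", gene_name, "' absent from mean_tpm: ",
         paste(missing_ids, collapse = ", "))
  vapply(stats::setNames(nm = c("A", "B", "D")), function(s)
    sum(mean_tpm[sub$raw_id[sub$effective_subgenome == s]]), numeric(1))
}

#' Relative subgenome expression fractions
#'
#' Expresses each subgenome total as a fraction of the gene's grand
#' total, i.e. relative A expression = total A tpm / (total A + total B
#' + total D tpm), and likewise for B and D. The fractions place the
#' triad on the 2-simplex used for balance classification.
#'
#' @param totals Numeric triple of non-negative totals (A, B, D order).
#' @return Named numeric vector \code{c(A = , B = , D = )} summing to 1.
#' @export
relative_fractions <- function(totals) {
  totals <- as.numeric(totals)
  stopifnot(length(totals) == 3L)
  if (any(totals < 0)) stop("subgenome totals must be non-negative")
  s <- sum(totals)
  if (s == 0)
    stop("fractions are undefined for an all-zero triad (total tpm is 0)")
  stats::setNames(totals / s, c("A", "B", "D"))
}

#' Log2 total triad expression
#'
#' log2 of the sum of the three subgenome totals, the magnitude scale
#' used to size symbols on ternary plots. No pseudocount is applied;
#' zero-total triads are excluded upstream rather than shifted.
#'
#' @param totals Numeric triple of non-negative totals.
#' @return log2(total A + total B + total D).
#' @export
log2_total <- function(totals) {
  totals <- as.numeric(totals)
  stopifnot(length(totals) == 3L)
  s <- sum(totals)
  if (s <= 0) stop("log2 total is undefined for an all-zero triad")
  log2(s)
}

#' Subgenome expression summary per gene per context
#'
#' Runs the full aggregation for every registry gene in every context:
#' mean tpm per locus over the context's samples, per-subgenome totals,
#' relative fractions, and log2 total. Gene-context pairs whose grand
#' total is zero have undefined fractions; they are returned in the
#' \code{dropped} attribute rather than silently discarded.
#'
#' @param matrix An \code{expression_matrix}.
#' @param registry A \code{triad_registry}.
#' @param contexts Named list of sample filters (see
#'   [mean_tpm_per_locus()]); the names label the contexts.
#' @param stratify_by_study Passed to [mean_tpm_per_locus()].
#' @return A data frame of class \code{subgenome_expression} with
#'   columns \code{gene_name}, \code{context}, \code{tissue},
#'   \code{condition} (single metadata value of the selected samples,
#'   or \code{"multiple"}), \code{total_A},
#'   \code{total_B}, \code{total_D}, \code{frac_A}, \code{frac_B},
#'   \code{frac_D}, \code{log2_total}, \code{n_samples}; zero-total
#'   pairs in \code{attr(, "dropped")}.
#' @export
analyze_gene_set <- function(matrix, registry, contexts,
                             stratify_by_study = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(registry, "triad_registry"))
  if (is.null(names(contexts)) || any(!nzchar(names(contexts))))
    stop("contexts must be a named list")
  genes <- unique(registry$gene_name)
  rows <- list()
  dropped <- list()
  label_of <- function(values) {
    u <- unique(values)
    if (length(u) == 1L) u else "multiple"
  }
  for (ctx in names(contexts)) {
    ids <- select_samples(matrix, contexts[[ctx]])
    sel <- matrix$sample_meta[matrix$sample_meta$sample_id %in% ids, ]
    mt <- mean_tpm_per_locus(matrix, contexts[[ctx]],
                             stratify_by_study = stratify_by_study)
    for (g in genes) {
      tot <- subgenome_totals(mt, registry, g)
      if (sum(tot) == 0) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(gene_name = g, context = ctx,
                     stringsAsFactors = FALSE)
        next
      }
      fr <- relative_fractions(tot)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_name = g, context = ctx,
        tissue = label_of(sel$tissue), condition = label_of(sel$condition),
        total_A = tot[["A"]], total_B = tot[["B"]], total_D = tot[["D"]],
        frac_A = fr[["A"]], frac_B = fr[["B"]], frac_D = fr[["D"]],
        log2_total = log2_total(tot),
        n_samples = length(ids),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_name = character(), context = character(),
               tissue = character(), condition = character(),
               total_A = numeric(), total_B = numeric(), total_D = numeric(),
               frac_A = numeric(), frac_B = numeric(), frac_D = numeric(),
               log2_total = numeric(), n_samples = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(gene_name = character(), context = character())
  class(out) <- c("subgenome_expression", "data.frame")
  out
}

#' Write a subgenome expression table to TSV
#'
#' Numeric columns are written with six decimal places.
#'
#' @param results A \code{subgenome_expression} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fractions <- function(results, path) {
  out <- as.data.frame(results)
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_samples"
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
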