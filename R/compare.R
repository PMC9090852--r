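#' Compare one gene's subgenome expression between two contexts
#'
#' Computes, for a single gene measured in two contexts (e.g. control
#' versus heat stress, or leaf versus spike), the shift in relative
#' subgenome fractions (a vector summing to zero), the fold change of
#' total triad expression (total_to / total_from, on the summed tpm
#' after subgenome aggregation) with its log2, and the balance-category
#' transition at a given boundary slack. \code{changed} is \code{TRUE}
#' exactly when the category differs between the two contexts; the two
#' boundary sets are carried along so near-boundary transitions can be
#' recognised as such.
#'
#' @param gene_results_from,gene_results_to Single rows of a
#'   \code{subgenome_expression} table (see [analyze_gene_set()]) for
#'   the same gene; both totals must be positive.
#' @param epsilon Boundary slack passed to [classify_balance()].
#' @return An object of class \code{shift_record}: list with
#'   \code{gene_name}, \code{context_from}, \code{context_to},
#'   \code{fractions_from}, \code{fractions_to}, \code{delta},
#'   \code{fold_change_total}, \code{log2_fold_change},
#'   \code{category_from}, \code{category_to}, \code{boundary_from},
#'   \code{boundary_to}, \code{changed}.
#' @export
compare_contexts <- function(gene_results_from, gene_results_to,
                             epsilon = 0.05) {
  from <- as.data.frame(gene_results_from)
  to <- as.data.frame(gene_results_to)
  stopifnot(nrow(from) == 1L, nrow(to) == 1L)
  if (!identical(from$gene_name, to$gene_name))
    stop("gene mismatch: '", from$gene_name, "' vs '", to$gene_name, "'")
  tot_from <- from$total_A + from$total_B + from$total_D
  tot_to <- to$total_A + to$total_B + to$total_D
  if (tot_from <= 0 || tot_to <= 0)
    stop("both contexts must have positive total expression for '",
         from$gene_name, "'")
  f_from <- c(A = from$frac_A, B = from$frac_B, D = from$frac_D)
  f_to <- c(A = to$frac_A, B = to$frac_B, D = to$frac_D)
  call_from <- classify_balance(f_from, epsilon)
  call_to <- classify_balance(f_to, epsilon)
  structure(list(
    gene_name = from$gene_name,
    context_from = from$context,
    context_to = to$context,
    fractions_from = f_from,
    fractions_to = f_to,
    delta = f_to - f_from,
    fold_change_total = tot_to / tot_from,
    log2_fold_change = log2(tot_to / tot_from),
    category_from = call_from$category,
    category_to = call_to$category,
    boundary_from = call_from$boundary_set,
    boundary_to = call_to$boundary_set,
    changed = call_from$category != call_to$category
  ), class = "shift_record")
}

#' Compare two subgenome expression tables gene by gene
#'
#' Runs [compare_contexts()] for every gene present in both tables and
#' partitions the genes into those whose balance category changed and
#' those whose did not. Genes present on only one side are reported,
#' never silently dropped.
#'
#' @param from_results,to_results \code{subgenome_expression} tables
#'   (one row per gene; if a table holds several contexts, filter it
#'   first).
#' @param epsilon Boundary slack passed to [classify_balance()].
#' @return A list with \code{shifts} (data frame, one row per shared
#'   gene, columns mirroring the shift record with \code{delta_A/B/D}
#'   and comma-joined boundary sets), \code{changed} and
#'   \code{unchanged} (character vectors of gene names), and
#'   \code{missing_from} / \code{missing_to} (genes absent from the
#'   respective side).
#' @export
compare_table <- function(from_results, to_results, epsilon = 0.05) {
  from <- as.data.frame(from_results)
  to <- as.data.frame(to_results)
  if (anyDuplicated(from$gene_name) || anyDuplicated(to$gene_name))
    stop("each table must have one row per gene; filter to one context first")
  shared <- intersect(from$gene_name, to$gene_name)
  if (length(shared) == 0L)
    stop("no genes shared between the two tables")
  recs <- lapply(shared, function(g)
    compare_contexts(from[from$gene_name == g, ], to[to$gene_name == g, ],
                     epsilon))
  shifts <- do.call(rbind, lapply(recs, function(r) data.frame(
    gene_name = r$gene_name,
    context_from = r$context_from, context_to = r$context_to,
    frac_A_from = r$fractions_from[["A"]],
    frac_B_from = r$fractions_from[["B"]],
    frac_D_from = r$fractions_from[["D"]],
    frac_A_to = r$fractions_to[["A"]],
    frac_B_to = r$fractions_to[["B"]],
    frac_D_to = r$fractions_to[["D"]],
    delta_A = r$delta[["A"]], delta_B = r$delta[["B"]],
    delta_D = r$delta[["D"]],
    fold_change_total = r$fold_change_total,
    log2_fold_change = r$log2_fold_change,
    category_from = r$category_from, category_to = r$category_to,
    boundary_from = paste(r$boundary_from, collapse = ","),
    boundary_to = paste(r$boundary_to, collapse = ","),
    changed = r$changed,
    stringsAsFactors = FALSE
  )))
  rownames(shifts) <- NULL
  list(shifts = shifts,
       changed = shifts$gene_name[shifts$changed],
       unchanged = shifts$gene_name[!shifts$changed],
       missing_from = setdiff(to$gene_name, from$gene_name),
       missing_to = setdiff(from$gene_name, to$gene_name))
}

#' @export
print.shift_record <- function(x, ...) {
  cat(sprintf("<shift_record> %s: %s -> %s\n", x$gene_name,
              x$context_from, x$context_to))
  cat(sprintf("  category %s -> %s (%s), total fold change %.3f\n",
              x$category_from, x$category_to,
              if (x$changed) "changed" else "unchanged",
              x$fold_change_total))
  invisible(x)
}
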