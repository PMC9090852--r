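#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#'   nucleotideSubstitutionMatrix readAAStringSet readDNAStringSet
#'   writeXStringSet AAStringSet DNAStringSet
NULL

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

default_scoring <- function(type) {
  # gap cost convention: a gap of length L costs gap_open + L * gap_extend
  if (type == "protein") {
    list(substitution_matrix = blosum62(), gap_open = -10, gap_extend = -1)
  } else {
    list(substitution_matrix =
           nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                        baseOnly = TRUE),
         gap_open = -5, gap_extend = -2)
  }
}

check_alphabet <- function(seq, alphabet, label) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d of %s",
                 chars[bad[1]], bad[1], label))
  invisible(seq)
}

#' Global pairwise alignment of two homoeolog sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' \pkg{Biostrings}. A gap of length L costs
#' \code{gap_open + L * gap_extend} (both negative). Defaults: BLOSUM62
#' with gap open -10 / extend -1 for protein; match 2 / mismatch -3 /
#' gap open -5 / extend -2 for nucleotide. The underlying dynamic
#' program returns one deterministic optimal alignment, so repeated
#' calls agree.
#'
#' @param seq_a,seq_b Non-empty sequence strings (upper case,
#'   single-letter codes).
#' @param type \code{"protein"} or \code{"nucleotide"}.
#' @param match,mismatch Nucleotide match/mismatch scores (ignored when
#'   \code{substitution_matrix} is supplied, or for protein input).
#' @param gap_open,gap_extend Gap penalties (non-positive).
#' @param substitution_matrix Optional substitution matrix overriding
#'   the type default.
#' @param id_a,id_b Sequence identifiers carried into the result.
#' @return An object of class \code{alignment_result}: list with
#'   \code{id_a}, \code{id_b}, \code{aligned_a}, \code{aligned_b}
#'   (equal-length gapped strings; removing \code{"-"} recovers the
#'   inputs and no column is gap-gap), \code{score} and
#'   \code{n_columns}.
#' @examples
#' aln <- global_align("ACGT", "AGT", type = "nucleotide")
#' percent_identity(aln)
#' @export
global_align <- function(seq_a, seq_b, type = c("protein", "nucleotide"),
                         match = NULL, mismatch = NULL,
                         gap_open = NULL, gap_extend = NULL,
                         substitution_matrix = NULL,
                         id_a = "seq_a", id_b = "seq_b") {
  type <- match.arg(type)
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty")
  def <- default_scoring(type)
  if (is.null(substitution_matrix)) {
    substitution_matrix <- if (type == "nucleotide" &&
                               !(is.null(match) && is.null(mismatch))) {
      nucleotideSubstitutionMatrix(match = if (is.null(match)) 2 else match,
                                   mismatch = if (is.null(mismatch)) -3 else mismatch,
                                   baseOnly = TRUE)
    } else def$substitution_matrix
  }
  if (is.null(gap_open)) gap_open <- def$gap_open
  if (is.null(gap_extend)) gap_extend <- def$gap_extend
  stopifnot(gap_open <= 0, gap_extend <= 0)

  alphabet <- rownames(substitution_matrix)
  check_alphabet(seq_a, alphabet, id_a)
  check_alphabet(seq_b, alphabet, id_b)

  as_bio <- if (type == "protein") Biostrings::AAString else Biostrings::DNAString
  aln <- pairwiseAlignment(as_bio(seq_a), as_bio(seq_b),
                           substitutionMatrix = substitution_matrix,
                           gapOpening = -gap_open, gapExtension = -gap_extend,
                           type = "global")
  aligned_a <- as.character(alignedPattern(aln))
  aligned_b <- as.character(alignedSubject(aln))
  structure(list(id_a = id_a, id_b = id_b,
                 aligned_a = unname(aligned_a), aligned_b = unname(aligned_b),
                 score = Biostrings::score(aln),
                 n_columns = nchar(aligned_a)),
            class = "alignment_result")
}

alignment_columns <- function(alignment) {
  stopifnot(inherits(alignment, "alignment_result"))
  list(a = strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]],
       b = strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]])
}

#' Percent identity of a global alignment
#'
#' 100 times the number of identical-residue columns over the total
#' number of alignment columns. Gap columns count in the denominator
#' (and never as identical), so indel-containing alignments are
#' penalised rather than ignored.
#'
#' @param alignment An \code{alignment_result} from [global_align()].
#' @return Percent identity in \code{[0, 100]}.
#' @export
percent_identity <- function(alignment) {
  cols <- alignment_columns(alignment)
  ident <- cols$a == cols$b & cols$a != "-"
  100 * sum(ident) / alignment$n_columns
}

#' Enumerate polymorphic columns of an alignment
#'
#' Lists every alignment column where the two sequences differ,
#' including indel columns (one residue against a gap). Positions are
#' 1-based in the respective ungapped sequences, \code{NA} at a gap.
#'
#' @param alignment An \code{alignment_result} from [global_align()].
#' @return Data frame with columns \code{column_index},
#'   \code{position_a}, \code{position_b}, \code{residue_a},
#'   \code{residue_b}, ordered by \code{column_index}; zero rows for
#'   identical sequences.
#' @export
list_polymorphisms <- function(alignment) {
  cols <- alignment_columns(alignment)
  pos_a <- ifelse(cols$a == "-", NA_integer_, cumsum(cols$a != "-"))
  pos_b <- ifelse(cols$b == "-", NA_integer_, cumsum(cols$b != "-"))
  diff <- which(cols$a != cols$b)
  data.frame(column_index = diff,
             position_a = pos_a[diff],
             position_b = pos_b[diff],
             residue_a = cols$a[diff],
             residue_b = cols$b[diff],
             stringsAsFactors = FALSE)
}

#' Mean pairwise identity of a sequence set
#'
#' Arithmetic mean of [percent_identity()] over all unordered pairs of
#' the input sequences, each pair aligned globally. This is the
#' "pairwise identity" summary used to support subgenome assignment of
#' unplaced loci (e.g. the three Raf2 homoeologs); it is not a
#' multiple-sequence-alignment column statistic.
#'
#' @param sequences Named character vector of two or more sequences.
#' @param ... Passed to [global_align()] (e.g. \code{type}).
#' @return Mean percent identity; the pairwise matrix is attached as
#'   attribute \code{"pairwise"}.
#' @export
mean_pairwise_identity <- function(sequences, ...) {
  if (length(sequences) < 2L)
    stop("need at least two sequences")
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  n <- length(sequences)
  pid <- matrix(100, n, n, dimnames = list(ids, ids))
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    p <- percent_identity(global_align(sequences[[i]], sequences[[j]],
                                       id_a = ids[i], id_b = ids[j], ...))
    pid[i, j] <- pid[j, i] <- p
    vals <- c(vals, p)
  }
  structure(mean(vals), pairwise = pid)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param type \code{"protein"} or \code{"nucleotide"}.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  set <- if (type == "protein") readAAStringSet(path) else
    readDNAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 60 columns.
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file path.
#' @param type \code{"protein"} or \code{"nucleotide"}.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequences, path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  set <- if (type == "protein") AAStringSet(sequences) else
    DNAStringSet(sequences)
  writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s vs %s: %d columns, score %.1f, %.1f%% identity\n",
              x$id_a, x$id_b, x$n_columns, x$score, percent_identity(x)))
  invisible(x)
}
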