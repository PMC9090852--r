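#' The seven expression-balance category centroids
#'
#' Triad expression balance is described by seven archetypes on the
#' 2-simplex of subgenome fractions (A, B, D): balanced expression at
#' the simplex centre; dominance of one subgenome, idealised as that
#' subgenome carrying all expression; and suppression of one subgenome,
#' idealised as the other two splitting expression equally. A fraction
#' triple is assigned to the nearest centroid (Euclidean distance in
#' fraction space), so the archetype coordinates induce the category
#' regions.
#'
#' @return A 7 x 3 numeric matrix; rows named \code{balanced},
#'   \code{A_dominant}, \code{B_dominant}, \code{D_dominant},
#'   \code{A_suppressed}, \code{B_suppressed}, \code{D_suppressed} (the
#'   fixed tie-break order), columns \code{A}, \code{B}, \code{D}. Each
#'   row sums to 1.
#' @export
balance_centroids <- function() {
  m <- rbind(
    balanced     = c(1, 1, 1) / 3,
    A_dominant   = c(1, 0, 0),
    B_dominant   = c(0, 1, 0),
    D_dominant   = c(0, 0, 1),
    A_suppressed = c(0, 1, 1) / 2,
    B_suppressed = c(1, 0, 1) / 2,
    D_suppressed = c(1, 1, 0) / 2
  )
  colnames(m) <- c("A", "B", "D")
  m
}

check_simplex <- function(fractions, tol = 1e-6) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L)
    stop("fractions must be a triple (A, B, D)")
  if (any(is.na(fractions)) || any(fractions < 0) ||
      abs(sum(fractions) - 1) > tol)
    stop("fractions must be non-negative and sum to 1 (got sum = ",
         format(sum(fractions)), ")")
  fractions
}

#' Classify a fraction triple into a balance category
#'
#' Assigns the triple to the nearest of the seven centroids (see
#' [balance_centroids()]) by Euclidean distance in the 3-D fraction
#' space; ties are broken by the fixed centroid order, so the call is
#' deterministic. Points near a category boundary are as informative as
#' the call itself: every centroid whose distance exceeds the minimum by
#' at most \code{epsilon} is reported in \code{boundary_set}, so a triad
#' sitting between (say) balanced expression, A/B suppression and D
#' dominance is surfaced rather than collapsed to a single label.
#'
#' @param fractions Numeric triple (A, B, D) on the simplex (sum 1
#'   within 1e-6).
#' @param epsilon Non-negative boundary slack in fraction-space
#'   distance; default 0.05.
#' @return An object of class \code{balance_call}: list with
#'   \code{fractions}, \code{category}, \code{distances} (named, all 7),
#'   \code{boundary_set} (category first, then the other near-minimal
#'   centroids in centroid order) and \code{ternary_xy}.
#' @examples
#' classify_balance(c(1, 1, 1) / 3)$category          # "balanced"
#' classify_balance(c(0.19, 0.16, 0.65), 0.06)$boundary_set
#' @export
classify_balance <- function(fractions, epsilon = 0.05) {
  f <- check_simplex(fractions)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  cen <- balance_centroids()
  d <- sqrt(rowSums((cen - matrix(f, nrow(cen), 3, byrow = TRUE))^2))
  category <- names(d)[which.min(d)]   # first minimum = fixed tie-break
  near <- names(d)[d <= min(d) + epsilon]
  boundary_set <- c(category, setdiff(near, category))
  structure(list(fractions = stats::setNames(f, c("A", "B", "D")),
                 category = category,
                 distances = d,
                 epsilon = epsilon,
                 boundary_set = boundary_set,
                 ternary_xy = ternary_xy(f)),
            class = "balance_call")
}

#' Ternary plot coordinates of a fraction triple
#'
#' Maps barycentric fractions to Cartesian coordinates in an equilateral
#' triangle with vertices A = (0, 0), B = (1, 0), D = (1/2, sqrt(3)/2)
#' (A bottom-left, B bottom-right, D top): x = fB + fD / 2,
#' y = fD * sqrt(3) / 2.
#'
#' @param fractions Numeric triple (A, B, D) on the simplex.
#' @return Named numeric vector \code{c(x = , y = )}.
#' @export
ternary_xy <- function(fractions) {
  f <- check_simplex(fractions)
  c(x = f[2] + f[3] / 2, y = f[3] * sqrt(3) / 2)
}

#' Classify a table of subgenome expression results
#'
#' Applies [classify_balance()] to each row of a
#' \code{subgenome_expression} table (or any data frame with
#' \code{frac_A}, \code{frac_B}, \code{frac_D} columns), preserving row
#' order.
#'
#' @param results Data frame with columns \code{frac_A}, \code{frac_B},
#'   \code{frac_D} (e.g. from [analyze_gene_set()]).
#' @param epsilon Boundary slack passed to [classify_balance()].
#' @return A data frame of class \code{balance_table}: the identifying
#'   columns of \code{results} plus \code{category}, one
#'   \code{dist_<centroid>} column per centroid, \code{boundary_set}
#'   (comma-joined), \code{ternary_x} and \code{ternary_y}.
#' @export
classify_table <- function(results, epsilon = 0.05) {
  results <- as.data.frame(results)
  need <- c("frac_A", "frac_B", "frac_D")
  if (!all(need %in% names(results)))
    stop("results must have columns frac_A, frac_B, frac_D")
  cen_names <- rownames(balance_centroids())
  dist_cols <- paste0("dist_", cen_names)
  calls <- lapply(seq_len(nrow(results)), function(i)
    classify_balance(unlist(results[i, need]), epsilon))
  keep <- intersect(c("gene_name", "context", "tissue", "condition",
                      "frac_A", "frac_B", "frac_D", "log2_total"),
                    names(results))
  out <- cbind(
    results[keep],
    data.frame(category = vapply(calls, `[[`, character(1), "category"),
               stringsAsFactors = FALSE),
    stats::setNames(as.data.frame(t(vapply(
      calls, function(cl) cl$distances, numeric(length(cen_names))))),
      dist_cols),
    data.frame(
      boundary_set = vapply(calls, function(cl)
        paste(cl$boundary_set, collapse = ","), character(1)),
      ternary_x = vapply(calls, function(cl) cl$ternary_xy[["x"]], numeric(1)),
      ternary_y = vapply(calls, function(cl) cl$ternary_xy[["y"]], numeric(1)),
      stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  class(out) <- c("balance_table", "data.frame")
  out
}

#' @export
print.balance_call <- function(x, ...) {
  cat(sprintf("<balance_call> %s  (A=%.3f B=%.3f D=%.3f)\n",
              x$category, x$fractions[1], x$fractions[2], x$fractions[3]))
  cat("  boundary set (epsilon=", format(x$epsilon), "): ",
      paste(x$boundary_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}
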