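#' Parse structured wheat gene identifiers
#'
#' Decomposes RefSeq-style hexaploid wheat Gene_IDs / Transcript_IDs
#' (e.g. \code{"TraesCS7A02G341000"}) into their constituent fields:
#' species code (\code{"Traes"}, Triticum aestivum), accession code
#' (\code{"CS"}, Chinese Spring), chromosome (1-7, or
#' \code{"unassigned"} for chromosome-"U" loci), subgenome (A/B/D, or
#' \code{"unknown"} for unassigned loci), assembly version (the opaque
#' two-digit segment, \code{"02"} for RefSeq v1.1), locus number
#' (kept as a string so leading zeros survive a round trip), and an
#' optional transcript isoform given as a decimal suffix
#' (\code{"TraesCS4A02G177500.2"} is isoform 2 of that locus).
#'
#' @param raw_id Character vector of one or more identifiers.
#' @return A data frame with one row per identifier and columns
#'   \code{raw_id}, \code{species_code}, \code{accession_code},
#'   \code{chromosome} (character: \code{"1"}..\code{"7"} or
#'   \code{"unassigned"}), \code{subgenome} (\code{"A"}, \code{"B"},
#'   \code{"D"} or \code{"unknown"}), \code{assembly_version},
#'   \code{locus_number} and \code{isoform} (integer, \code{NA} when the
#'   identifier carries no decimal suffix).
#' @seealso [format_gene_id()] for the inverse operation.
#' @examples
#' parse_gene_id("TraesCS7A02G341000")
#' parse_gene_id("TraesCSU02G129700")   # unassigned chromosome
#' @export
parse_gene_id <- function(raw_id) {
  stopifnot(is.character(raw_id), length(raw_id) >= 1L)
  if (any(is.na(raw_id) | !nzchar(raw_id)))
    stop("gene identifiers must be non-empty strings")
  rows <- lapply(raw_id, parse_gene_id_one)
  do.call(rbind, rows)
}

parse_gene_id_one <- function(id) {
  rx <- "^Traes([A-Z]+?)(U|[1-7][ABD])([0-9]{2})G([0-9]+)(\\.([0-9]+))?$"
  m <- regmatches(id, regexec(rx, id))[[1]]
  if (length(m) == 0L) stop(describe_gene_id_error(id))
  chrom_tok <- m[3]
  unassigned <- identical(chrom_tok, "U")
  data.frame(
    raw_id = id,
    species_code = "Traes",
    accession_code = m[2],
    chromosome = if (unassigned) "unassigned" else substr(chrom_tok, 1, 1),
    subgenome = if (unassigned) "unknown" else substr(chrom_tok, 2, 2),
    assembly_version = m[4],
    locus_number = m[5],
    isoform = if (nzchar(m[7])) as.integer(m[7]) else NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Build a parse-error message that names the first offending segment.
describe_gene_id_error <- function(id) {
  if (!startsWith(id, "Traes"))
    return(sprintf("malformed gene id '%s': missing 'Traes' species prefix", id))
  rest <- substring(id, 6L)
  if (!grepl("G", rest, fixed = TRUE))
    return(sprintf("malformed gene id '%s': missing 'G' locus segment", id))
  tail <- sub("^.*?G", "", rest)
  if (!grepl("^[0-9]+(\\.[0-9]+)?$", tail))
    return(sprintf("malformed gene id '%s': non-numeric locus number '%s'", id, tail))
  head <- sub("G[0-9]+(\\.[0-9]+)?$", "", rest)
  if (!grepl("^[A-Z]+?(U|[1-7][ABD])[0-9]{2}$", head))
    return(sprintf(
      "malformed gene id '%s': segment '%s' is not <accession><chromosome+subgenome|U><version>",
      id, head))
  sprintf("malformed gene id '%s'", id)
}

#' Serialize parsed gene loci back to identifiers
#'
#' Inverse of [parse_gene_id()]: reconstructs each raw identifier from its
#' parsed fields, including the isoform suffix when present. Parsing then
#' formatting is the identity on any well-formed identifier.
#'
#' @param locus A data frame as returned by [parse_gene_id()].
#' @return Character vector of identifiers.
#' @export
format_gene_id <- function(locus) {
  chrom_tok <- ifelse(locus$chromosome == "unassigned", "U",
                      paste0(locus$chromosome, locus$subgenome))
  id <- paste0(locus$species_code, locus$accession_code, chrom_tok,
               locus$assembly_version, "G", locus$locus_number)
  ifelse(is.na(locus$isoform), id, paste0(id, ".", locus$isoform))
}

#' Load and validate a triad registry
#'
#' Reads a table mapping gene names to subgenome-resolved gene loci, the
#' package's representation of a set of homoeolog triads. Each gene_id is
#' parsed with [parse_gene_id()]; the subgenome used in all downstream
#' aggregation (\code{effective_subgenome}) is the one parsed from the
#' identifier unless an explicit override assigns one. Loci on the
#' unassigned chromosome ("U") have no parseable subgenome and are
#' rejected unless overridden: a subgenome call for an unplaced locus is
#' a documented assumption (typically supported by sequence identity, see
#' [mean_pairwise_identity()]), never a silent guess.
#'
#' A gene is expected to have at least one locus on each of A, B and D;
#' a gene violating this raises a warning but still loads, since partial
#' triads are biologically real (gene loss, incomplete assemblies).
#'
#' @param table_source Path to a TSV with columns \code{gene_name} and
#'   \code{gene_id} (optional third column \code{subgenome_override}),
#'   or an equivalent data frame.
#' @param overrides Optional named character vector mapping gene_id to a
#'   subgenome in \code{A}, \code{B}, \code{D}. Every name must be an ID
#'   present in the table. Merged with any \code{subgenome_override}
#'   column.
#' @return An object of class \code{triad_registry}: a data frame with
#'   one row per locus and columns \code{gene_name}, \code{raw_id}, the
#'   parsed fields, \code{effective_subgenome}, \code{override_flag} and
#'   \code{override_note}.
#' @examples
#' reg <- rubiscosome_registry()
#' count_loci(reg)                 # 70
#' count_loci(reg, "RbcS", "A")    # 9
#' @export
load_registry <- function(table_source, overrides = NULL) {
  tab <- if (is.character(table_source)) {
    utils::read.delim(table_source, stringsAsFactors = FALSE,
                      colClasses = "character")
  } else {
    as.data.frame(table_source, stringsAsFactors = FALSE)
  }
  required <- c("gene_name", "gene_id")
  if (nrow(tab) == 0L && !all(required %in% names(tab))) {
    tab <- data.frame(gene_name = character(), gene_id = character())
  }
  if (!all(required %in% names(tab)))
    stop("registry table must have columns gene_name and gene_id")

  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene_id in registry table: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))

  ov <- character()
  if ("subgenome_override" %in% names(tab)) {
    has <- !is.na(tab$subgenome_override) & nzchar(tab$subgenome_override)
    ov <- stats::setNames(tab$subgenome_override[has], tab$gene_id[has])
  }
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named character vector (gene_id -> subgenome)")
    ov[names(overrides)] <- overrides
  }
  if (length(ov)) {
    missing_ids <- setdiff(names(ov), tab$gene_id)
    if (length(missing_ids))
      stop("override for gene_id absent from table: ",
           paste(missing_ids, collapse = ", "))
    bad <- !ov %in% c("A", "B", "D")
    if (any(bad))
      stop("override subgenome must be A, B or D (got: ",
           paste(unique(ov[bad]), collapse = ", "), ")")
  }

  if (nrow(tab) == 0L) {
    reg <- cbind(
      data.frame(gene_name = character()),
      parse_gene_id("TraesCS1A02G000000")[0, ],
      data.frame(effective_subgenome = character(),
                 override_flag = logical(),
                 override_note = character())
    )
    class(reg) <- c("triad_registry", "data.frame")
    return(reg)
  }

  parsed <- parse_gene_id(tab$gene_id)
  eff <- parsed$subgenome
  idx <- match(parsed$raw_id, names(ov))
  has_ov <- !is.na(idx)
  eff[has_ov] <- unname(ov[idx[has_ov]])

  unknown <- eff == "unknown"
  if (any(unknown))
    stop("loci with unknown subgenome and no override: ",
         paste(parsed$raw_id[unknown], collapse = ", "))

  flag <- eff != parsed$subgenome
  note <- ifelse(flag,
                 paste0("parsed subgenome '", parsed$subgenome,
                        "' overridden to '", eff, "'"),
                 NA_character_)

  reg <- cbind(data.frame(gene_name = tab$gene_name,
                          stringsAsFactors = FALSE),
               parsed,
               data.frame(effective_subgenome = eff,
                          override_flag = flag,
                          override_note = note,
                          stringsAsFactors = FALSE))

  # warn (not error) on incomplete triads: the registry must still load
  for (g in unique(reg$gene_name)) {
    present <- unique(reg$effective_subgenome[reg$gene_name == g])
    absent <- setdiff(c("A", "B", "D"), present)
    if (length(absent))
      warning(sprintf("gene '%s' has no locus in subgenome(s): %s",
                      g, paste(absent, collapse = ", ")),
              call. = FALSE)
  }

  rownames(reg) <- NULL
  class(reg) <- c("triad_registry", "data.frame")
  reg
}

#' The packaged Rubiscosome triad registry
#'
#' Loads the registry of the 70 wheat gene loci encoding the Rubiscosome
#' -- the nuclear-encoded proteins required for Rubisco biogenesis and
#' function (RbcS, the chaperonins Cpn60/Cpn20, the assembly chaperones
#' RbcX, Raf1, Raf2 and Bsd2, the activases Rca1/Rca2, and the inhibitor
#' phosphatases CA1Pase and XuBPase) -- shipped with the package as a
#' plain TSV. The one locus on the unassigned chromosome
#' (TraesCSU02G129700) carries an explicit override assigning it to the
#' D subgenome as the Raf2 homoeolog, a call supported by its 95.9\%
#' mean pairwise protein identity with the placed A and B copies.
#'
#' @return A \code{triad_registry} (see [load_registry()]) with 70 loci
#'   over 11 genes.
#' @export
rubiscosome_registry <- function() {
  path <- system.file("extdata", "rubiscosome_triads.tsv",
                      package = "triadbalance", mustWork = TRUE)
  load_registry(path)
}

#' Count registry loci, optionally filtered
#'
#' @param registry A \code{triad_registry}.
#' @param gene_name Optional gene name to restrict to; an unknown name
#'   is an error (a misspelling should not silently count zero).
#' @param subgenome Optional subgenome in \code{A}, \code{B}, \code{D}.
#' @return Number of matching loci.
#' @export
count_loci <- function(registry, gene_name = NULL, subgenome = NULL) {
  stopifnot(inherits(registry, "triad_registry"))
  keep <- rep(TRUE, nrow(registry))
  if (!is.null(gene_name)) {
    if (!gene_name %in% registry$gene_name)
      stop("unknown gene name: ", gene_name)
    keep <- keep & registry$gene_name == gene_name
  }
  if (!is.null(subgenome)) {
    subgenome <- match.arg(subgenome, c("A", "B", "D"))
    keep <- keep & registry$effective_subgenome == subgenome
  }
  sum(keep)
}

#' Group registry loci by gene and subgenome
#'
#' @param registry A \code{triad_registry}.
#' @return A named list (one element per gene, in order of first
#'   appearance) of lists with elements \code{A}, \code{B}, \code{D},
#'   each a character vector of locus IDs. The groups partition the
#'   registry: every locus appears in exactly one.
#' @export
group_by_gene <- function(registry) {
  stopifnot(inherits(registry, "triad_registry"))
  genes <- unique(registry$gene_name)
  out <- lapply(genes, function(g) {
    sub <- registry[registry$gene_name == g, ]
    lapply(stats::setNames(nm = c("A", "B", "D")), function(s)
      sub$raw_id[sub$effective_subgenome == s])
  })
  stats::setNames(out, genes)
}

#' @export
`[.triad_registry` <- function(x, ...) {
  # a subset is no longer a validated registry; return a plain frame
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.triad_registry <- function(x, ...) {
  cat(sprintf("<triad_registry> %d loci, %d genes, %d override(s)\n",
              nrow(x), length(unique(x$gene_name)), sum(x$override_flag)))
  print.data.frame(utils::head(as.data.frame(x)[c(
    "gene_name", "raw_id", "chromosome", "effective_subgenome",
    "override_flag")], 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
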