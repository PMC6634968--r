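# Reading/writing of alignments, trees, region tables and annotation tables,
# region slicing in reference coordinates, and the ortholog-set filters.
# Internal coordinate convention: 0-based, half-open [start, end).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
GAP <- "-"

#' Construct a table of protein regions
#'
#' Regions are stored 0-based, half-open: a region `[start, end)` of length
#' `end - start`. This is the single internal convention; readers of 1-based
#' inclusive tables convert at the boundary (see [read_regions()]).
#'
#' @param protein_id character vector of protein identifiers.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param kind `"disordered"` or `"ordered"`.
#' @param region_id optional region identifiers; defaults to
#'   `<protein>_<start>_<end>`.
#' @return data.frame with columns `region_id`, `protein_id`, `start`, `end`,
#'   `kind`.
#' @export
idr_regions <- function(protein_id, start, end, kind = "disordered",
                        region_id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L) || any(start >= end))
    stop("invalid region coordinates: need 0 <= start < end")
  kind <- match.arg(kind, c("disordered", "ordered"), several.ok = TRUE)
  kind <- rep_len(kind, length(protein_id))
  if (is.null(region_id))
    region_id <- paste(protein_id, start, end, sep = "_")
  data.frame(region_id = region_id, protein_id = protein_id,
             start = start, end = end, kind = kind,
             stringsAsFactors = FALSE)
}

#' Construct an aligned ortholog set
#'
#' @param rows named character vector of equal-length gapped amino-acid
#'   strings (alphabet ACDEFGHIKLMNPQRSTVWY plus `-`); names are species.
#' @param idr_id identifier for the region this alignment covers.
#' @param reference_species name of the reference row (defaults to the first).
#' @param region optional 1-row region table giving the reference coordinates.
#' @return object of class `ortholog_set`.
#' @export
ortholog_set <- function(rows, idr_id = "idr", reference_species = NULL,
                         region = NULL) {
  if (is.list(rows)) rows <- unlist(rows)
  if (length(rows) == 0L) stop("ortholog set needs at least one row")
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("rows must be uniquely named by species")
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("alignment rows have unequal length (ragged alignment)")
  rows <- toupper(rows)
  bad <- grepl(sprintf("[^%s%s]", paste(AA20, collapse = ""), GAP), rows)
  if (any(bad))
    stop("rows contain characters outside the amino-acid alphabet + gap: ",
         paste(names(rows)[bad], collapse = ", "))
  if (is.null(reference_species)) reference_species <- names(rows)[1L]
  if (!reference_species %in% names(rows))
    stop("reference species not present in rows")
  structure(list(idr_id = idr_id, rows = rows,
                 reference_species = reference_species, region = region),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("<ortholog_set> %s: %d species, width %d, reference %s\n",
              x$idr_id, length(x$rows), nchar(x$rows[[1L]]),
              x$reference_species))
  invisible(x)
}

n_species <- function(set) length(set$rows)
ungapped <- function(s) gsub(GAP, "", s, fixed = TRUE)

#' Read a gapped FASTA alignment as an ortholog set
#'
#' @param path FASTA file of aligned (gapped) amino-acid sequences.
#' @param recode_ambiguous if `TRUE`, non-standard residues (B, J, O, U, X, Z)
#'   are recoded to gaps; the default rejects them, because downstream feature
#'   values are composition-sensitive.
#' @inheritParams ortholog_set
#' @return an `ortholog_set`.
#' @export
read_alignment <- function(path, idr_id = sub("\\.[^.]*$", "", basename(path)),
                           reference_species = NULL,
                           recode_ambiguous = FALSE) {
  aln <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e)))
  if (length(aln) == 0L) stop("empty FASTA file: ", path)
  rows <- toupper(as.character(aln))
  names(rows) <- sub("\\s.*$", "", names(aln))
  rows <- gsub(".", GAP, rows, fixed = TRUE)
  if (recode_ambiguous) rows <- gsub("[BJOUXZ]", GAP, rows)
  if (length(unique(nchar(rows))) != 1L)
    stop("records in '", path, "' have unequal lengths (not an alignment)")
  ortholog_set(rows, idr_id = idr_id, reference_species = reference_species)
}

#' Read ungapped sequences from FASTA (no alignment-width constraint)
#'
#' @inheritParams read_alignment
#' @return named character vector of uppercased sequences.
#' @export
read_sequences <- function(path, recode_ambiguous = FALSE) {
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(aln))
  names(seqs) <- sub("\\s.*$", "", names(aln))
  if (recode_ambiguous) seqs <- gsub("[BJOUXZ]", "", seqs)
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs)
  if (any(bad))
    stop("sequences contain characters outside the amino-acid alphabet: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

# Map ungapped reference positions (0-based) to alignment columns (1-based).
reference_columns <- function(set) {
  ref <- strsplit(set$rows[[set$reference_species]], "")[[1L]]
  which(ref != GAP)
}

#' Slice a region out of a full-protein alignment
#'
#' Columns returned are exactly those between the alignment columns of
#' reference residues `start` and `end - 1` inclusive; gap-only columns
#' interior to the span are retained because they carry indel information.
#'
#' @param set an `ortholog_set` whose reference row spans the full protein.
#' @param region 1-row region table (0-based half-open, reference ungapped
#'   coordinates), or `NULL` to use `start`/`end` directly.
#' @param start,end 0-based half-open coordinates, used when `region` is NULL.
#' @return an `ortholog_set` restricted to the region's columns.
#' @export
slice_region <- function(set, region = NULL, start = NULL, end = NULL) {
  if (!is.null(region)) { start <- region$start[1L]; end <- region$end[1L] }
  refcols <- reference_columns(set)
  if (is.null(start) || is.null(end) || start >= end)
    stop("coordinate error: need start < end")
  if (start < 0L || end > length(refcols))
    stop("coordinate error: region [", start, ",", end,
         ") outside reference ungapped length ", length(refcols))
  cols <- refcols[start + 1L]:refcols[end]
  rows <- vapply(set$rows, function(s)
    paste(strsplit(s, "")[[1L]][cols], collapse = ""), character(1L))
  out <- ortholog_set(rows, idr_id = set$idr_id,
                      reference_species = set$reference_species,
                      region = region)
  out
}

#' Keep regions of at least a minimum length
#'
#' @param regions region table from [idr_regions()] or [read_regions()].
#' @param min_length minimum region length in residues (default 30).
#' @return the filtered region table, order preserved.
#' @export
filter_regions <- function(regions, min_length = 30L) {
  regions[(regions$end - regions$start) >= min_length, , drop = FALSE]
}

#' Apply the per-ortholog-set inclusion filters
#'
#' Rows whose ungapped length is below `min_residues` are dropped; if fewer
#' than `min_species` rows remain the whole set is rejected. Rejection is a
#' return state (class `idr_rejected`), not an error.
#'
#' @param set an `ortholog_set`.
#' @param min_species minimum species retained (default 10).
#' @param min_residues minimum ungapped residues per species (default 10).
#' @return the filtered `ortholog_set`, or an `idr_rejected` object whose
#'   `reason` field records why.
#' @export
filter_ortholog_set <- function(set, min_species = 10L, min_residues = 10L) {
  keep <- nchar(ungapped(set$rows)) >= min_residues
  if (sum(keep) < min_species)
    return(rejected(set$idr_id, sprintf(
      "only %d species with >= %d residues (need %d)",
      sum(keep), min_residues, min_species)))
  out <- set
  out$rows <- set$rows[keep]
  if (!out$reference_species %in% names(out$rows))
    return(rejected(set$idr_id, "reference species dropped by residue filter"))
  out
}

rejected <- function(id, reason)
  structure(list(id = id, reason = reason), class = "idr_rejected")

#' @rdname filter_ortholog_set
#' @param x object to test.
#' @export
is_rejected <- function(x) inherits(x, "idr_rejected")

#' Fraction of a query region covered by a union of target regions
#'
#' @param query 1-row region table.
#' @param targets region table on the same protein (may be empty).
#' @return fraction in `[0, 1]`: covered positions / query length.
#' @export
overlap_fraction <- function(query, targets) {
  if (nrow(targets) > 0L && any(targets$protein_id != query$protein_id[1L]))
    stop("overlap_fraction: query and targets must share protein_id")
  qs <- query$start[1L]; qe <- query$end[1L]
  if (nrow(targets) == 0L) return(0)
  covered <- logical(qe - qs)
  for (i in seq_len(nrow(targets))) {
    a <- max(qs, targets$start[i]); b <- min(qe, targets$end[i])
    if (a < b) covered[(a - qs + 1L):(b - qs)] <- TRUE
  }
  mean(covered)
}

#' Read a Newick tree
#'
#' @param path Newick file with branch lengths in substitutions/site.
#' @return an `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("cannot parse Newick '", path, "': ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("cannot parse Newick '", path, "'")
  if (is.null(tr$edge.length)) stop("tree '", path, "' has no branch lengths")
  if (any(tr$edge.length < 0)) stop("tree '", path, "' has negative branch lengths")
  tr
}

#' Read a region table (TSV)
#'
#' Expects a header with columns `protein_id`, `start`, `end` and optionally
#' `kind` and `region_id`.
#'
#' @param path tab-delimited file.
#' @param one_based if `TRUE` the file uses 1-based inclusive coordinates
#'   (SGD convention) and is converted to the internal 0-based half-open
#'   convention on read.
#' @return region table as from [idr_regions()].
#' @export
read_regions <- function(path, one_based = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("region table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  start <- as.integer(df$start); end <- as.integer(df$end)
  if (one_based) start <- start - 1L
  idr_regions(df$protein_id, start, end,
              kind = if ("kind" %in% names(df)) df$kind else "disordered",
              region_id = if ("region_id" %in% names(df)) df$region_id)
}

#' Read a protein-to-annotation table (TSV)
#'
#' Expects columns `protein_id`, `term_id` and optionally `term_class`
#' (GO / phenotype / literature). Duplicate (protein, term) rows are
#' deduplicated; term sizes are recomputed from the deduplicated table.
#'
#' @param path tab-delimited file.
#' @return an `annotation_table`: deduplicated data.frame with attribute
#'   `term_sizes`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "term_id")
  if (!all(need %in% names(df)))
    stop("annotation table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  if (!"term_class" %in% names(df)) df$term_class <- "GO"
  annotation_table(df)
}

#' @rdname read_annotations
#' @param df data.frame with columns `protein_id`, `term_id`, `term_class`.
#' @export
annotation_table <- function(df) {
  if (!"term_class" %in% names(df)) df$term_class <- "GO"
  df <- unique(df[, c("protein_id", "term_id", "term_class")])
  attr(df, "term_sizes") <- table(df$term_id)
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @rdname read_annotations
#' @param tab an `annotation_table`.
#' @export
term_sizes <- function(tab) {
  sz <- attr(tab, "term_sizes")
  if (is.null(sz)) sz <- table(tab$term_id)
  sz
}

#' Write / read a labelled numeric matrix (Cluster 3.0-compatible layout)
#'
#' Tab-delimited text with one header row and one leading label column
#' (`UID`); an optional per-row weight column (`GWEIGHT`) follows the labels.
#' Missing values are written as empty cells.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param weights optional per-row weights.
#' @export
write_matrix <- function(mat, path, weights = NULL) {
  header <- c("UID", if (!is.null(weights)) "GWEIGHT", colnames(mat))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  body <- format(mat, trim = TRUE, digits = 15)
  body[is.na(mat)] <- ""
  for (i in seq_len(nrow(mat))) {
    fields <- c(rownames(mat)[i],
                if (!is.null(weights)) format(weights[i], digits = 15),
                body[i, ])
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @return `read_matrix`: the matrix, with weights (if present) in attribute
#'   `"weights"`.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "UID") stop("matrix file '", path, "' lacks UID column")
  rn <- df[[1L]]; df <- df[, -1L, drop = FALSE]
  w <- NULL
  if (ncol(df) > 0L && names(df)[1L] == "GWEIGHT") {
    w <- as.numeric(df[[1L]]); df <- df[, -1L, drop = FALSE]
  }
  mat <- as.matrix(df)
  mat[mat == ""] <- NA
  mode(mat) <- "numeric"
  rownames(mat) <- rn
  attr(mat, "weights") <- w
  mat
}
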