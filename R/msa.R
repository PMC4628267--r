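#' @importFrom stats plogis qlogis hclust cutree as.dist kmeans setNames
#' @importFrom utils read.table write.table
NULL

#' Amino-acid alphabet
#'
#' The 20 standard amino-acid one-letter codes used throughout the package.
#' Gaps are represented by `"-"` (a `"."` in input files is normalized to
#' `"-"` on read).
#'
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Construct a protein multiple alignment
#'
#' An `aa_msa` holds aligned homologous protein sequences, one of which is a
#' designated query (wild-type) row. All rows must have equal width, ids must
#' be unique, and residues must come from the 20-letter alphabet plus the gap
#' symbol.
#'
#' @param seqs named character vector of aligned sequences (equal width), or a
#'   character matrix of single residues with row names.
#' @param query id or row index of the wild-type (query) sequence.
#' @return an object of class `aa_msa` with elements `mat` (residue matrix),
#'   `query` (row index).
#' @export
aa_msa <- function(seqs, query = 1L) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    if (length(seqs) == 0L) stop("empty alignment")
    ids <- names(seqs)
    if (is.null(ids) || anyNA(ids) || any(ids == "")) {
      stop("all sequences must be named")
    }
    w <- unique(nchar(seqs))
    if (length(w) != 1L) stop("all rows must have the same width")
    if (w == 0L) stop("empty alignment")
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mat) <- ids
  }
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty alignment")
  if (anyDuplicated(rownames(mat))) stop("sequence ids must be unique")
  mat[mat == "."] <- GAP_CHAR
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET20, GAP_CHAR))
  if (length(bad)) {
    stop("illegal characters in alignment: ", paste(bad, collapse = ", "))
  }
  if (is.character(query)) {
    query <- match(query, rownames(mat))
    if (is.na(query)) stop("query id not found in alignment")
  }
  query <- as.integer(query)
  if (length(query) != 1L || is.na(query) || query < 1L || query > nrow(mat)) {
    stop("query index out of range")
  }
  structure(list(mat = mat, query = query), class = "aa_msa")
}

#' @export
print.aa_msa <- function(x, ...) {
  cat(sprintf("aa_msa: %d sequences x %d columns (query: %s)\n",
              nrow(x$mat), ncol(x$mat), rownames(x$mat)[x$query]))
  invisible(x)
}

#' @export
dim.aa_msa <- function(x) dim(x$mat)

msa_ids <- function(msa) rownames(msa$mat)
msa_width <- function(msa) ncol(msa$mat)
query_id <- function(msa) rownames(msa$mat)[msa$query]

## subset rows/columns, keeping the query row tracked
msa_subset <- function(msa, rows = NULL, cols = NULL) {
  mat <- msa$mat
  qid <- query_id(msa)
  if (!is.null(rows)) mat <- mat[rows, , drop = FALSE]
  if (!is.null(cols)) mat <- mat[, cols, drop = FALSE]
  q <- match(qid, rownames(mat))
  if (is.na(q)) stop("query row lost in subsetting")
  aa_msa(mat, query = q)
}

#' Remove redundant sequences from an alignment
#'
#' Greedy redundancy filter in input order: each row is compared against the
#' already retained rows; if the pairwise identity of a pair exceeds
#' `identity_threshold`, the sequence with fewer non-gap residues is
#' discarded (on a length tie, the row appearing later in input order).
#' Pairwise identity is the fraction of matching residues over columns where
#' both sequences are non-gap. The query row is never discarded.
#'
#' @param msa an [aa_msa()].
#' @param identity_threshold fraction in (0, 1]; pairs strictly above it are
#'   considered redundant. Default 0.95.
#' @return filtered `aa_msa`.
#' @export
remove_redundant <- function(msa, identity_threshold = 0.95) {
  stopifnot(inherits(msa, "aa_msa"))
  if (!is.numeric(identity_threshold) || length(identity_threshold) != 1L ||
      identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  mat <- msa$mat
  n <- nrow(mat)
  nongap <- mat != GAP_CHAR
  len <- rowSums(nongap)
  pid <- function(i, j) {
    both <- nongap[i, ] & nongap[j, ]
    ov <- sum(both)
    if (ov == 0L) return(0)
    sum(mat[i, both] == mat[j, both]) / ov
  }
  retained <- integer(0)
  for (i in seq_len(n)) {
    drop_i <- FALSE
    for (j in retained) {
      if (pid(i, j) > identity_threshold) {
        if (i == msa$query) {
          retained <- setdiff(retained, j)        # query always wins
        } else if (j == msa$query) {
          drop_i <- TRUE; break
        } else if (len[i] > len[j]) {
          retained <- setdiff(retained, j)        # candidate longer: keep it
        } else {
          drop_i <- TRUE; break                   # shorter or tie: drop later row
        }
      }
    }
    if (!drop_i) retained <- c(retained, i)
  }
  msa_subset(msa, rows = sort(retained))
}

#' Drop low-quality (gappy) columns
#'
#' Removes columns whose gap fraction exceeds `max_gap_fraction` and returns
#' the filtered alignment together with an old-to-new column index map so that
#' variant columns can be re-located after filtering.
#'
#' @param msa an [aa_msa()].
#' @param max_gap_fraction columns with gap fraction strictly above this are
#'   dropped. Default 0.99.
#' @return list with `msa` (filtered alignment) and `column_map` (integer
#'   vector over old columns; `NA` marks a removed column).
#' @export
filter_columns <- function(msa, max_gap_fraction = 0.99) {
  stopifnot(inherits(msa, "aa_msa"))
  if (!is.numeric(max_gap_fraction) || max_gap_fraction < 0 || max_gap_fraction > 1) {
    stop("max_gap_fraction must be in [0, 1]")
  }
  gapfrac <- colMeans(msa$mat == GAP_CHAR)
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep)) stop("no informative columns")
  column_map <- rep(NA_integer_, msa_width(msa))
  column_map[keep] <- seq_len(sum(keep))
  list(msa = msa_subset(msa, cols = which(keep)), column_map = column_map)
}

## ---- variant specifications ------------------------------------------------

#' Parse a variant string
#'
#' Variants use the conventional `"A95E"` notation: wild-type residue,
#' 1-based position in the ungapped query sequence, mutant residue.
#'
#' @param x character like `"A95E"`, or the three parts given separately via
#'   `wt`, `position`, `mut`.
#' @param wt,position,mut alternative component-wise specification.
#' @return an object of class `variant_spec`.
#' @export
parse_variant <- function(x = NULL, wt = NULL, position = NULL, mut = NULL) {
  if (!is.null(x)) {
    if (inherits(x, "variant_spec")) return(x)
    m <- regmatches(x, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x))[[1]]
    if (length(m) != 4L) stop("cannot parse variant string: ", x)
    wt <- toupper(m[2]); position <- as.integer(m[3]); mut <- toupper(m[4])
  }
  if (!wt %in% AA_ALPHABET20) stop("wild-type residue not a standard amino acid: ", wt)
  if (!mut %in% AA_ALPHABET20) stop("mutant residue not a standard amino acid: ", mut)
  if (identical(wt, mut)) stop("wild-type and mutant residues must differ")
  position <- as.integer(position)
  if (is.na(position) || position < 1L) stop("variant position must be >= 1")
  structure(list(wt = wt, position = position, mut = mut), class = "variant_spec")
}

#' @export
format.variant_spec <- function(x, ...) paste0(x$wt, x$position, x$mut)

#' @export
print.variant_spec <- function(x, ...) {
  cat("variant:", format(x), "\n"); invisible(x)
}

#' @export
as.character.variant_spec <- function(x, ...) format(x)

#' Locate a variant's alignment column
#'
#' Finds the column holding the `position`-th non-gap residue of the query row
#' and verifies that it equals the stated wild-type residue.
#'
#' @param msa an [aa_msa()].
#' @param variant a [parse_variant()] object or string.
#' @return 1-based column index.
#' @export
map_variant_to_column <- function(msa, variant) {
  stopifnot(inherits(msa, "aa_msa"))
  variant <- parse_variant(variant)
  qrow <- msa$mat[msa$query, ]
  resid_cols <- which(qrow != GAP_CHAR)
  if (variant$position > length(resid_cols)) {
    stop(sprintf("variant position %d beyond query length %d",
                 variant$position, length(resid_cols)))
  }
  col <- resid_cols[variant$position]
  if (qrow[col] != variant$wt) {
    stop(sprintf("wild-type residue mismatch at position %d: query has %s, variant says %s",
                 variant$position, qrow[col], variant$wt))
  }
  col
}

## ---- region selection ------------------------------------------------------

#' Select the alignment region around a variant
#'
#' Builds a window by alternating left-first/right extension from the variant
#' column. The primary extension only passes columns where the query row is
#' non-gap; if both directions are blocked (query gaps or alignment edges)
#' before `min_width` columns are collected, extension continues through
#' columns whose overall gap fraction is below `extension_gap_fraction`.
#' Rows that are entirely gaps inside the window are dropped (the query row
#' is always retained).
#'
#' @param msa an [aa_msa()].
#' @param variant_column 1-based column index of the variant (the query must
#'   be non-gap there).
#' @param min_width minimum number of window columns (default 10).
#' @param extension_gap_fraction gap-fraction bound for the secondary
#'   extension (default 0.10).
#' @return an object of class `msa_window`: list with `msa` (the windowed
#'   sub-alignment), `first`, `last` (1-based inclusive source columns) and
#'   `variant_column` (source coordinates).
#' @export
select_region <- function(msa, variant_column, min_width = 10L,
                          extension_gap_fraction = 0.10) {
  stopifnot(inherits(msa, "aa_msa"))
  w <- msa_width(msa)
  if (variant_column < 1L || variant_column > w) stop("variant column out of range")
  if (min_width < 1L) stop("min_width must be >= 1")
  qrow <- msa$mat[msa$query, ]
  if (qrow[variant_column] == GAP_CHAR) {
    stop("query row is a gap at the variant column")
  }
  gapfrac <- colMeans(msa$mat == GAP_CHAR)

  left <- right <- variant_column
  extend <- function(passable) {
    ## alternate left, then right, one column at a time
    repeat {
      if (right - left + 1L >= min_width) break
      moved <- FALSE
      if (left > 1L && passable(left - 1L)) { left <<- left - 1L; moved <- TRUE }
      if (right - left + 1L >= min_width) break
      if (right < w && passable(right + 1L)) { right <<- right + 1L; moved <- TRUE }
      if (!moved) break
    }
  }
  extend(function(col) qrow[col] != GAP_CHAR)
  if (right - left + 1L < min_width) {
    extend(function(col) gapfrac[col] < extension_gap_fraction)
  }

  sub <- msa_subset(msa, cols = left:right)
  all_gap <- rowSums(sub$mat != GAP_CHAR) == 0L
  all_gap[sub$query] <- FALSE
  if (any(all_gap)) sub <- msa_subset(sub, rows = which(!all_gap))
  structure(list(msa = sub, first = left, last = right,
                 variant_column = variant_column),
            class = "msa_window")
}

#' Treat a whole alignment as a window
#'
#' Convenience wrapper used when clustering a full alignment rather than a
#' variant-centered region.
#'
#' @param msa an [aa_msa()].
#' @param variant_column optional source column of a variant of interest.
#' @return an `msa_window` spanning all columns.
#' @export
as_window <- function(msa, variant_column = NA_integer_) {
  stopifnot(inherits(msa, "aa_msa"))
  structure(list(msa = msa, first = 1L, last = msa_width(msa),
                 variant_column = as.integer(variant_column)),
            class = "msa_window")
}

#' @export
print.msa_window <- function(x, ...) {
  cat(sprintf("msa_window: columns %d-%d (%d rows), variant column %s\n",
              x$first, x$last, nrow(x$msa$mat),
              ifelse(is.na(x$variant_column), "none", x$variant_column)))
  invisible(x)
}

## column index of the variant inside the window, 1-based
window_variant_offset <- function(window) {
  if (is.na(window$variant_column)) stop("window has no variant column")
  window$variant_column - window$first + 1L
}
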