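#' Read an aligned protein FASTA or Stockholm file
#'
#' Thin wrapper around [Biostrings::readAAMultipleAlignment()]. Gap symbols
#' `.` are normalized to `-`; Stockholm annotation lines are ignored by the
#' reader.
#'
#' @param path file path.
#' @param query id (or row index) of the wild-type sequence.
#' @param format `"fasta"` or `"stockholm"`.
#' @return an [aa_msa()].
#' @export
read_alignment <- function(path, query = 1L, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  seqs <- if (format == "fasta") {
    as.character(Biostrings::readAAStringSet(path))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = format)
    as.character(Biostrings::unmasked(aln))
  }
  aa_msa(seqs, query = query)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa an [aa_msa()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "aa_msa"))
  seqs <- apply(msa$mat, 1L, paste, collapse = "")
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export / import a cluster partition as TSV
#'
#' Two-column tab-separated table: sequence id, cluster label.
#'
#' @param partition a `cluster_partition` (see [ceo_cluster()]).
#' @param path file path.
#' @return `path` invisibly (`write_partition`), or a `cluster_partition`
#'   (`read_partition`).
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "cluster_partition"))
  df <- data.frame(id = names(partition$labels), cluster = partition$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @param query_id id of the query sequence (defines the target cluster when
#'   reading a partition back in).
#' @export
read_partition <- function(path, query_id) {
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = c("character", "integer"))
  labels <- df$cluster
  names(labels) <- df$id
  new_partition(labels, query_id)
}

#' Dump / load a profile HMM as plain text
#'
#' Writes the model dimensions, match and insert emission tables, and the
#' three transition tables as labelled TSV blocks separated by `#` headers.
#'
#' @param hmm a `profile_hmm` (see [build_profile()]).
#' @param path file path.
#' @export
write_profile <- function(hmm, path) {
  stopifnot(inherits(hmm, "profile_hmm"))
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# profile_hmm n_match=%d\n", hmm$n_match), file = con)
  blocks <- list(match_emissions = hmm$match_em, insert_emissions = hmm$insert_em,
                 trans_from_match = hmm$trans$M, trans_from_insert = hmm$trans$I,
                 trans_from_delete = hmm$trans$D,
                 background = matrix(hmm$background, nrow = 1,
                                     dimnames = list(NULL, AA_ALPHABET20)))
  for (nm in names(blocks)) {
    cat(sprintf("# %s\n", nm), file = con)
    out <- blocks[[nm]]
    storage.mode(out) <- "character"   # full-precision, unpadded cells
    write.table(out, con, sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  n_match <- as.integer(sub(".*n_match=", "", lines[hdr[1]]))
  parse_block <- function(name) {
    i <- grep(paste0("^# ", name, "$"), lines)
    stopifnot(length(i) == 1L)
    j <- c(hdr[hdr > i], length(lines) + 1L)[1] - 1L
    tab <- read.table(text = lines[(i + 1L):j], sep = "\t", header = TRUE,
                      row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    storage.mode(m) <- "double"
    m
  }
  structure(list(
    n_match = n_match,
    match_em = parse_block("match_emissions"),
    insert_em = parse_block("insert_emissions"),
    trans = list(M = parse_block("trans_from_match"),
                 I = parse_block("trans_from_insert"),
                 D = parse_block("trans_from_delete")),
    background = as.numeric(parse_block("background")[1, ])
  ), class = "profile_hmm")
}
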