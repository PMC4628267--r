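## ---- profile HMM construction ----------------------------------------------

#' Build a profile HMM from a subfamily cluster
#'
#' Columns whose gap fraction within the cluster is at most
#' `match_gap_threshold` become match states; residues in non-match columns
#' are emitted by the flanking insert state. Emissions use Laplace-style
#' pseudocounts, `(count + pseudocount) / (n + 20 * pseudocount)`, and
#' transitions are estimated from the observed per-row state paths with the
#' same pseudocount over each state's allowed successors. The background
#' model is uniform over the 20 residues unless given.
#'
#' @param window an `msa_window`.
#' @param cluster_rows ids (or indices) of the cluster's rows; at least 2.
#' @param pseudocount positive pseudocount (default 1).
#' @param match_gap_threshold maximal gap fraction of a match column
#'   (default 0.5).
#' @param background optional length-20 residue probability vector.
#' @return an object of class `profile_hmm` with match/insert emission
#'   matrices, transition matrices from match/insert/delete states, the
#'   background distribution, and `n_match`.
#' @export
build_profile <- function(window, cluster_rows, pseudocount = 1,
                          match_gap_threshold = 0.5, background = NULL) {
  stopifnot(inherits(window, "msa_window"))
  mat <- window$msa$mat
  if (is.character(cluster_rows)) {
    idx <- match(cluster_rows, rownames(mat))
    if (anyNA(idx)) stop("unknown cluster row ids")
  } else idx <- as.integer(cluster_rows)
  if (length(idx) < 2L) stop("subfamily too small: clusters of size 1 cannot support a profile")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  sub <- mat[idx, , drop = FALSE]
  nseq <- nrow(sub)

  gapfrac <- colMeans(sub == GAP_CHAR)
  is_match <- gapfrac <= match_gap_threshold
  L <- sum(is_match)
  if (L < 1L) stop("no match columns in cluster")
  match_cols <- which(is_match)
  ## insert segment index for every column: residues in non-match columns
  ## belong to insert state j = number of match columns to their left (0..L)
  seg <- cumsum(is_match)

  pc <- pseudocount
  match_em <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET20))
  for (j in seq_len(L)) {
    res <- sub[, match_cols[j]]
    res <- res[res != GAP_CHAR]
    cnt <- tabulate(match(res, AA_ALPHABET20), nbins = 20L)
    match_em[j, ] <- (cnt + pc) / (length(res) + 20 * pc)
  }
  insert_em <- matrix(0, L + 1L, 20L, dimnames = list(NULL, AA_ALPHABET20))
  for (j in 0:L) {
    cols <- which(!is_match & seg == j)
    res <- as.vector(sub[, cols])
    res <- res[res != GAP_CHAR]
    cnt <- tabulate(match(res, AA_ALPHABET20), nbins = 20L)
    insert_em[j + 1L, ] <- (cnt + pc) / (length(res) + 20 * pc)
  }

  ## transition counts from observed state paths; states indexed by their
  ## match coordinate j = 0..L (M0 = begin, ML+1 = end); successors of any
  ## state at j are {M_{j+1} ("M"), I_j ("I"), D_{j+1} ("D")}; at j = L the
  ## delete successor does not exist and "M" means the end state.
  succ <- c("M", "I", "D")
  cntM <- matrix(0, L + 1L, 3L, dimnames = list(NULL, succ))
  cntI <- matrix(0, L + 1L, 3L, dimnames = list(NULL, succ))
  cntD <- matrix(0, L + 1L, 3L, dimnames = list(NULL, succ))   # row j+1: D_j (D_0 unused)
  for (r in seq_len(nseq)) {
    ## state path of this row: begin, then one state per residue/gap event
    types <- "M"
    for (cc in seq_len(ncol(sub))) {
      if (is_match[cc]) {
        types <- c(types, if (sub[r, cc] == GAP_CHAR) "D" else "M")
      } else if (sub[r, cc] != GAP_CHAR) {
        types <- c(types, "I")
      }
    }
    ## match coordinate along the path (increments on M and D states)
    js <- integer(length(types)); j <- 0L
    for (s in seq_along(types)) {
      if (s > 1L && types[s] %in% c("M", "D")) j <- j + 1L
      js[s] <- j
    }
    types <- c(types, "M"); js <- c(js, L + 1L)   # end state
    for (s in seq_len(length(types) - 1L)) {
      row <- js[s] + 1L
      nxt <- types[s + 1L]
      if (types[s] == "M") cntM[row, nxt] <- cntM[row, nxt] + 1
      else if (types[s] == "I") cntI[row, nxt] <- cntI[row, nxt] + 1
      else cntD[row, nxt] <- cntD[row, nxt] + 1
    }
  }
  norm_rows <- function(cnt) {
    pr <- cnt + pc
    pr[L + 1L, "D"] <- 0                      # no delete state past L
    pr / rowSums(pr)
  }
  trans <- list(M = norm_rows(cntM), I = norm_rows(cntI), D = norm_rows(cntD))
  trans$D[1L, ] <- NA                          # D_0 does not exist

  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-9) {
    stop("background must be a length-20 probability vector")
  }
  structure(list(n_match = L, match_em = match_em, insert_em = insert_em,
                 trans = trans, background = background),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm: %d match states\n", x$n_match))
  invisible(x)
}

## ---- forward scoring --------------------------------------------------------

#' Log-odds bit score of a sequence against a profile HMM
#'
#' Full-sequence (global) forward algorithm in log space: the score is
#' `log2` of the total probability of the sequence under the profile divided
#' by its probability under the background model. Finite for any sequence
#' length reachable through delete and insert paths.
#'
#' @param hmm a `profile_hmm`.
#' @param sequence residue string (no gaps) over the 20-letter alphabet.
#' @return bit score (numeric scalar).
#' @export
sequence_bitscore <- function(hmm, sequence) {
  stopifnot(inherits(hmm, "profile_hmm"))
  x <- strsplit(toupper(sequence), "")[[1]]
  if (length(x) == 0L) stop("empty sequence")
  xi <- match(x, AA_ALPHABET20)
  if (anyNA(xi)) stop("illegal character in sequence: ", paste(unique(x[is.na(xi)]), collapse = ""))
  n <- length(xi); L <- hmm$n_match

  lt <- lapply(hmm$trans, function(m) suppressWarnings(log(m)))
  lem <- log(hmm$match_em); lei <- log(hmm$insert_em)
  NEG <- -Inf
  ## fM[i+1, j+1]: log prob of first i symbols ending in M_j (M_0 = begin);
  ## fI[i+1, j+1]: ... ending in I_j; fD[i+1, j+1]: ... ending in D_j
  fM <- matrix(NEG, n + 1L, L + 1L)
  fI <- matrix(NEG, n + 1L, L + 1L)
  fD <- matrix(NEG, n + 1L, L + 1L)
  fM[1L, 1L] <- 0
  ## deletes reachable with zero symbols emitted
  for (j in seq_len(L)) {
    from_m <- fM[1L, j] + lt$M[j, "D"]
    from_d <- if (j >= 2L) fD[1L, j] + lt$D[j, "D"] else NEG
    fD[1L, j + 1L] <- logsumexp(c(from_m, from_d))
  }
  for (i in seq_len(n)) {
    for (j in 0:L) {
      jj <- j + 1L
      if (j >= 1L) {
        prev <- c(fM[i, jj - 1L] + lt$M[jj - 1L, "M"],
                  fI[i, jj - 1L] + lt$I[jj - 1L, "M"],
                  if (j >= 2L) fD[i, jj - 1L] + lt$D[jj - 1L, "M"] else NEG)
        fM[i + 1L, jj] <- lem[j, xi[i]] + logsumexp(prev)
      }
      prev <- c(fM[i, jj] + lt$M[jj, "I"],
                fI[i, jj] + lt$I[jj, "I"],
                if (j >= 1L) fD[i, jj] + lt$D[jj, "I"] else NEG)
      fI[i + 1L, jj] <- lei[jj, xi[i]] + logsumexp(prev)
    }
    for (j in seq_len(L)) {
      jj <- j + 1L
      prev <- c(fM[i + 1L, jj - 1L] + lt$M[jj - 1L, "D"],
                fI[i + 1L, jj - 1L] + lt$I[jj - 1L, "D"],
                if (j >= 2L) fD[i + 1L, jj - 1L] + lt$D[jj - 1L, "D"] else NEG)
      fD[i + 1L, jj] <- logsumexp(prev)
    }
  }
  logp <- logsumexp(c(fM[n + 1L, L + 1L] + lt$M[L + 1L, "M"],
                      fI[n + 1L, L + 1L] + lt$I[L + 1L, "M"],
                      fD[n + 1L, L + 1L] + lt$D[L + 1L, "M"]))
  lognull <- sum(log(hmm$background[xi]))
  (logp - lognull) / log(2)
}

## ---- variant scoring --------------------------------------------------------

#' Damage score of a single substitution against one profile
#'
#' Compares the fit of the wild-type and mutant sequences to a subfamily
#' profile. In `difference` mode (default) the score is
#' `bitscore(wild) - bitscore(mutant)`; in `ratio` mode it is their
#' quotient. Larger scores mean the mutant fits this subfamily worse than
#' the wild type; scores below the neutral fixed point (0 for difference,
#' 1 for ratio) mean the mutant fits better, the regime underlying gain
#' calls.
#'
#' @param hmm a `profile_hmm`.
#' @param wild,mutant equal-length residue strings differing at exactly one
#'   position.
#' @param mode `"difference"` or `"ratio"`.
#' @return numeric score.
#' @export
hmmvar_score <- function(hmm, wild, mutant, mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  if (identical(wild, mutant)) stop("wild and mutant sequences are identical")
  w <- strsplit(wild, "")[[1]]; m <- strsplit(mutant, "")[[1]]
  if (length(w) != length(m) || sum(w != m) != 1L) {
    stop("wild and mutant must differ at exactly one position")
  }
  bw <- sequence_bitscore(hmm, wild)
  bm <- sequence_bitscore(hmm, mutant)
  if (mode == "difference") {
    bw - bm
  } else {
    if (abs(bm) < 1e-12) stop("undefined ratio: mutant bit score is zero")
    bw / bm
  }
}

#' Assemble a per-cluster variant score set
#'
#' Given per-cluster scores (cluster 0 being the target cluster that contains
#' the wild-type sequence), records the target score, the minimum score over
#' the non-target clusters and which cluster attains it.
#'
#' @param per_cluster_score named numeric vector; names are cluster labels
#'   ("0", "1", ...), label "0" required.
#' @param no_call logical flag for insignificant bit scores.
#' @return an object of class `variant_score_set`.
#' @export
variant_score_set <- function(per_cluster_score, no_call = FALSE) {
  if (!"0" %in% names(per_cluster_score)) stop("target cluster score (label 0) required")
  others <- per_cluster_score[names(per_cluster_score) != "0"]
  if (length(others)) {
    amin <- names(others)[which.min(others)]
    min_other <- unname(others[[amin]])
  } else {
    amin <- NA_character_; min_other <- NA_real_
  }
  structure(list(per_cluster_score = per_cluster_score,
                 target_score = unname(per_cluster_score[["0"]]),
                 min_other_score = min_other,
                 argmin_cluster = amin,
                 no_call = isTRUE(no_call)),
            class = "variant_score_set")
}

#' @export
print.variant_score_set <- function(x, ...) {
  cat(sprintf("variant_score_set: S0 = %.4g, Sx = %.4g (cluster %s)%s\n",
              x$target_score, x$min_other_score, x$argmin_cluster,
              if (x$no_call) " [no call]" else ""))
  invisible(x)
}

#' Score a variant against every eligible subfamily profile
#'
#' Builds one profile HMM per cluster of size greater than one, extracts the
#' query's ungapped window sequence as the wild type, substitutes the mutant
#' residue at the variant column, and scores the pair against every profile.
#' The call is flagged insignificant (`no_call`) when both wild and mutant
#' bit scores fall below `significance_floor` against every eligible profile.
#' If ratio mode is requested and any mutant bit score is zero, all clusters
#' are rescored in difference mode (recorded in `mode_used`).
#'
#' @param window an `msa_window` carrying the variant column.
#' @param partition a `cluster_partition` over the window rows; the target
#'   cluster (label 0) must have size > 1.
#' @param variant a [parse_variant()] object or string; its wild-type residue
#'   must match the query at the variant column.
#' Non-target clusters contribute to the minimum score only if they have at
#' least `min_donor_size` rows. A single substitution can change a
#' difference-mode score by at most `log2((n + pseudocount) / pseudocount)`
#' for a cluster of n rows, so clusters below `pseudocount * (2^t - 1)` rows
#' can never reach a cutoff t: they would vote "acquire" as pure prior
#' rather than evidence. The pipeline derives `min_donor_size` from the
#' cutoff accordingly; the standalone default keeps every cluster of size
#' greater than one.
#'
#' @param significance_floor bit-score floor defining an insignificant call
#'   (default 0).
#' @param mode score mode, see [hmmvar_score()].
#' @param pseudocount,match_gap_threshold passed to [build_profile()].
#' @param min_donor_size minimum rows for a non-target cluster to enter the
#'   minimum score (default 2).
#' @return a [variant_score_set()] with extra fields `bitscores` (per-cluster
#'   wild/mutant bits) and `mode_used`.
#' @export
score_variant_across_clusters <- function(window, partition, variant,
                                          significance_floor = 0,
                                          mode = c("difference", "ratio"),
                                          pseudocount = 1,
                                          match_gap_threshold = 0.5,
                                          min_donor_size = 2L) {
  mode <- match.arg(mode)
  variant <- parse_variant(variant)
  labels <- check_partition(window, partition)
  msa <- window$msa
  qrow <- msa$mat[msa$query, ]
  off <- window_variant_offset(window)
  if (qrow[off] == GAP_CHAR) stop("query is gapped at the variant column")
  pos_in_window <- sum(qrow[seq_len(off)] != GAP_CHAR)
  wild_vec <- qrow[qrow != GAP_CHAR]
  if (wild_vec[pos_in_window] != variant$wt) {
    stop("wild-type residue mismatch inside the window")
  }
  mut_vec <- wild_vec
  mut_vec[pos_in_window] <- variant$mut
  wild <- paste(wild_vec, collapse = "")
  mutant <- paste(mut_vec, collapse = "")

  sizes <- table(labels)
  if (is.na(sizes["0"]) || sizes[["0"]] < 2L) {
    stop("target cluster has size 1; cannot score")
  }
  eligible <- names(sizes)[sizes > 1L &
                             (names(sizes) == "0" | sizes >= min_donor_size)]
  hmms <- lapply(eligible, function(lab) {
    build_profile(window, names(labels)[labels == as.integer(lab)],
                  pseudocount = pseudocount,
                  match_gap_threshold = match_gap_threshold)
  })
  names(hmms) <- eligible
  bits <- vapply(hmms, function(h) {
    c(wild = sequence_bitscore(h, wild), mutant = sequence_bitscore(h, mutant))
  }, numeric(2))

  score_all <- function(md) {
    vapply(eligible, function(lab) {
      bw <- bits["wild", lab]; bm <- bits["mutant", lab]
      if (md == "difference") bw - bm
      else {
        if (abs(bm) < 1e-12) stop("undefined ratio: mutant bit score is zero")
        bw / bm
      }
    }, numeric(1))
  }
  mode_used <- mode
  scores <- tryCatch(score_all(mode), error = function(e) {
    if (mode == "ratio") {
      mode_used <<- "difference"
      warning("zero mutant bit score; falling back to difference mode")
      score_all("difference")
    } else stop(e)
  })
  no_call <- all(bits["wild", ] < significance_floor &
                   bits["mutant", ] < significance_floor)
  out <- variant_score_set(scores, no_call = no_call)
  out$bitscores <- bits
  out$mode_used <- mode_used
  out$wild <- wild
  out$mutant <- mutant
  out
}
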