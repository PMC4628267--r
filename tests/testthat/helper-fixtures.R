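## shared fixtures and independent oracles

make_msa <- function(seqs, query = 1L) {
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  aa_msa(seqs, query = query)
}

## a two-block alignment: `n_per` rows each of two fully conserved,
## mutually distinct sequences (query = first row of block 1)
two_block_msa <- function(n_per = 3L, a = "ACDEF", b = "WYKLM") {
  seqs <- c(setNames(rep(a, n_per), paste0("a", seq_len(n_per))),
            setNames(rep(b, n_per), paste0("b", seq_len(n_per))))
  aa_msa(seqs, query = 1L)
}

manual_partition <- function(labels, ids) {
  names(labels) <- ids
  structure(list(labels = labels, k = length(unique(labels)),
                 target_label = 0L,
                 sizes = as.integer(table(labels))),
            class = "cluster_partition")
}

## hand-built profile HMM with forced match-to-match transitions
flat_hmm <- function(L, match_em = NULL) {
  tr <- matrix(0, L + 1L, 3L, dimnames = list(NULL, c("M", "I", "D")))
  tr[, "M"] <- 1
  if (is.null(match_em)) {
    match_em <- matrix(1 / 20, L, 20, dimnames = list(NULL, AA_ALPHABET20))
  }
  structure(list(
    n_match = L,
    match_em = match_em,
    insert_em = matrix(1 / 20, L + 1L, 20, dimnames = list(NULL, AA_ALPHABET20)),
    trans = list(M = tr, I = tr, D = tr),
    background = rep(1 / 20, 20)), class = "profile_hmm")
}

## independent forward oracle: explicit enumeration of every state path.
## States are (type, j): begin = ("M", 0), end = ("M", L + 1); successors of
## any state at j are M_{j+1}, I_j, D_{j+1}. Returns total path probability.
brute_force_forward <- function(hmm, sequence) {
  x <- match(strsplit(sequence, "")[[1]], AA_ALPHABET20)
  n <- length(x); L <- hmm$n_match
  tr_prob <- function(type, j, nxt) {
    m <- hmm$trans[[type]][j + 1L, nxt]
    if (is.na(m)) 0 else m
  }
  rec <- function(type, j, pos) {
    ## probability of emitting x[pos..n] and reaching the end state,
    ## starting from state (type, j) already entered (symbol consumed)
    total <- 0
    ## to end
    if (j == L && pos == n + 1L) total <- total + tr_prob(type, j, "M")
    ## to M_{j+1} (emits one symbol)
    if (j < L && pos <= n) {
      total <- total + tr_prob(type, j, "M") *
        hmm$match_em[j + 1L, x[pos]] * rec("M", j + 1L, pos + 1L)
    }
    ## to I_j (emits one symbol)
    if (pos <= n) {
      total <- total + tr_prob(type, j, "I") *
        hmm$insert_em[j + 1L, x[pos]] * rec("I", j, pos + 1L)
    }
    ## to D_{j+1} (silent)
    if (j < L) {
      total <- total + tr_prob(type, j, "D") * rec("D", j + 1L, pos)
    }
    total
  }
  rec("M", 0L, 1L)
}

brute_force_bitscore <- function(hmm, sequence) {
  x <- match(strsplit(sequence, "")[[1]], AA_ALPHABET20)
  p <- brute_force_forward(hmm, sequence)
  unname(log2(p / prod(hmm$background[x])))
}

expect_partition_equal <- function(partition, truth) {
  ari <- mclust::adjustedRandIndex(partition$labels[names(truth)], truth)
  expect_equal(ari, 1)
}
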