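## run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## integer-encode a window's residues: 1..20 amino acids, 21 = gap
encode_window <- function(window) {
  stopifnot(inherits(window, "msa_window"))
  mat <- window$msa$mat
  enc <- match(mat, c(AA_ALPHABET20, GAP_CHAR))
  dim(enc) <- dim(mat)
  rownames(enc) <- rownames(mat)
  enc
}

## pairwise p-distance: mismatch fraction over columns where both rows are
## non-gap; rows with no overlap get the maximal distance 1
p_distance <- function(mat) {
  n <- nrow(mat)
  nongap <- mat != GAP_CHAR
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- nongap[i, ] & nongap[j, ]
      ov <- sum(both)
      d[i, j] <- d[j, i] <-
        if (ov == 0L) 1 else sum(mat[i, both] != mat[j, both]) / ov
    }
  }
  d
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
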