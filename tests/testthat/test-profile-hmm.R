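test_that("profile construction applies Laplace pseudocounts and the match rule", {
  ## gap-free 4-row cluster: column with counts {A:4} -> P(A) = 5/24
  m <- make_msa(c(q = "AAAAAAA", a = "AAAAAAA", b = "AAAAAAA", c = "AAAAAAA"))
  w <- as_window(m)
  hmm <- build_profile(w, rownames(m$mat))
  expect_equal(hmm$n_match, 7L)                      # gap-free width 7
  expect_equal(unname(hmm$match_em[1, "A"]), 5 / 24)
  expect_equal(unname(hmm$match_em[1, "C"]), 1 / 24)

  ## a column with 60% gaps is not a match state at threshold 0.5
  m2 <- make_msa(c(q = "AC", a = "A-", b = "A-", c = "A-", d = "AC"))
  hmm2 <- build_profile(as_window(m2), rownames(m2$mat))
  expect_equal(hmm2$n_match, 1L)

  ## size-1 clusters are rejected
  expect_error(build_profile(w, "q"), "subfamily too small")
})

test_that("emission and transition rows are proper distributions", {
  set.seed(5)
  seqs <- vapply(1:6, function(i) {
    paste(sample(c(AA_ALPHABET20[1:6], "-"), 15,
                 replace = TRUE, prob = c(rep(0.13, 6), 0.22)), collapse = "")
  }, character(1))
  seqs[1] <- paste(sample(AA_ALPHABET20[1:6], 15, replace = TRUE), collapse = "")
  m <- make_msa(seqs)
  hmm <- build_profile(as_window(m), rownames(m$mat))
  expect_true(all(abs(rowSums(hmm$match_em) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm$insert_em) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm$trans$M) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm$trans$I) - 1) < 1e-9))
  expect_true(all(abs(rowSums(hmm$trans$D[-1, , drop = FALSE]) - 1) < 1e-9))
})

test_that("a background-equal model with forced matches scores zero bits", {
  hmm <- flat_hmm(3)
  for (s in c("ACD", "WYK", "LLL")) {
    expect_equal(sequence_bitscore(hmm, s), 0)
  }
  expect_error(sequence_bitscore(hmm, "AXB"), "illegal character")
  expect_error(sequence_bitscore(hmm, ""), "empty")
})

test_that("the forward score matches exhaustive path enumeration", {
  set.seed(9)
  seqs <- c(q = "ACDEF", a = "AC-EF", b = "WCDEF", c = "ACDEY")
  m <- make_msa(seqs)
  hmm <- build_profile(as_window(m), rownames(m$mat))
  for (s in c("ACDEF", "ACD", "ACDEFWW", "W")) {
    expect_equal(sequence_bitscore(hmm, s), brute_force_bitscore(hmm, s),
                 tolerance = 1e-10)
  }
})

test_that("a conserved model ranks the consensus above all substitution neighbors", {
  ## width-5 model, each match column 0.9 on its consensus residue
  consensus <- c("A", "C", "D", "E", "F")
  em <- matrix(0.1 / 19, 5, 20, dimnames = list(NULL, AA_ALPHABET20))
  for (j in 1:5) em[j, consensus[j]] <- 0.9
  hmm <- flat_hmm(5, match_em = em)
  s0 <- sequence_bitscore(hmm, paste(consensus, collapse = ""))
  for (j in 1:5) {
    for (res in setdiff(AA_ALPHABET20, consensus[j])) {
      neighbor <- consensus
      neighbor[j] <- res
      expect_lt(sequence_bitscore(hmm, paste(neighbor, collapse = "")), s0)
    }
  }
})

test_that("scoring is deterministic and invariant to row order within a cluster", {
  fam <- simulate_family(family_model(seed = 6))
  w <- as_window(fam$msa)
  rows <- rownames(w$msa$mat)[1:12]
  h1 <- build_profile(w, rows)
  h2 <- build_profile(w, rev(rows))
  seq <- paste(w$msa$mat[1, ], collapse = "")
  expect_identical(sequence_bitscore(h1, seq), sequence_bitscore(h1, seq))
  expect_equal(sequence_bitscore(h1, seq), sequence_bitscore(h2, seq))
})

test_that("log-space forward stays finite for very long sequences", {
  hmm <- flat_hmm(5)
  ## force a small self-loop so long sequences are reachable
  hmm$trans$M[, "I"] <- 0.1; hmm$trans$M[, "M"] <- 0.9
  hmm$trans$I[, "I"] <- 0.5; hmm$trans$I[, "M"] <- 0.5
  long <- paste(rep("A", 10000), collapse = "")
  expect_true(is.finite(sequence_bitscore(hmm, long)))
})

test_that("hmmvar_score applies the difference and ratio contracts", {
  consensus <- "ACDEF"
  em <- matrix(0.1 / 19, 5, 20, dimnames = list(NULL, AA_ALPHABET20))
  for (j in 1:5) em[j, substr(consensus, j, j)] <- 0.9
  hmm <- flat_hmm(5, match_em = em)
  wild <- "ACDEF"; mutant <- "ACDEW"
  bw <- sequence_bitscore(hmm, wild); bm <- sequence_bitscore(hmm, mutant)
  expect_equal(hmmvar_score(hmm, wild, mutant, mode = "difference"), bw - bm)
  expect_equal(hmmvar_score(hmm, wild, mutant, mode = "ratio"), bw / bm)
  expect_gt(hmmvar_score(hmm, wild, mutant), 0)   # conserved column: damaging
  ## mutant fitting better flips the sign convention
  expect_lt(hmmvar_score(hmm, mutant, wild, mode = "difference"), 0)
  expect_error(hmmvar_score(hmm, wild, wild), "identical")
  expect_error(hmmvar_score(hmm, "ACDEF", "WWDEF"), "exactly one position")
  ## zero mutant bit score: ratio undefined
  flat <- flat_hmm(5)
  expect_error(hmmvar_score(flat, wild, mutant, mode = "ratio"), "undefined ratio")
  expect_equal(hmmvar_score(flat, wild, mutant, mode = "difference"), 0)
})

test_that("variant score sets record min/argmin over non-target clusters", {
  s <- variant_score_set(c("0" = 2.9, "1" = 0.5, "2" = -3.1))
  expect_equal(s$target_score, 2.9)
  expect_equal(s$min_other_score, -3.1)
  expect_equal(s$argmin_cluster, "2")
  expect_false(s$no_call)

  ## no non-target cluster: min marked absent
  s0 <- variant_score_set(c("0" = 1.2))
  expect_true(is.na(s0$min_other_score))
  expect_error(variant_score_set(c("1" = 1)), "target cluster")
})

test_that("cross-cluster scoring flags no-calls and respects donor eligibility", {
  fam <- simulate_family(family_model(seed = 11))
  p <- plant_variant(fam, "GoF")
  col <- map_variant_to_column(fam$msa, p$variant)
  w <- select_region(fam$msa, col)
  part <- ceo_cluster(w, restarts = 2, seed = 11)
  sc <- score_variant_across_clusters(w, part, p$variant)
  ## planted gain: the mutant fits another subfamily better than the target
  expect_lt(sc$min_other_score, sc$target_score)
  expect_false(sc$no_call)

  ## an absurdly high floor turns every call insignificant
  sc_hi <- score_variant_across_clusters(w, part, p$variant,
                                         significance_floor = 1e6)
  expect_true(sc_hi$no_call)

  ## donor clusters below min_donor_size are excluded from the minimum
  sizes <- table(part$labels)
  big <- max(sizes[names(sizes) != "0"])
  sc_excl <- score_variant_across_clusters(w, part, p$variant,
                                           min_donor_size = big + 1L)
  expect_true(is.na(sc_excl$min_other_score))

  ## target cluster of size 1 cannot be scored
  labels <- part$labels
  labels[] <- seq_along(labels)
  lone <- manual_partition(labels - 1L, names(labels))
  expect_error(score_variant_across_clusters(w, lone, p$variant),
               "size 1")
})

test_that("profiles round-trip through the plain-text dump", {
  m <- make_msa(c(q = "AC-EF", a = "ACDEF", b = "ACDEY", c = "AC-EF"))
  hmm <- build_profile(as_window(m), rownames(m$mat))
  path <- tempfile(fileext = ".txt")
  write_profile(hmm, path)
  back <- read_profile(path)
  expect_equal(back$n_match, hmm$n_match)
  expect_equal(unname(back$match_em), unname(hmm$match_em), tolerance = 1e-12)
  expect_equal(unname(back$trans$M), unname(hmm$trans$M), tolerance = 1e-12)
  seq <- "ACDEF"
  expect_equal(sequence_bitscore(back, seq), sequence_bitscore(hmm, seq),
               tolerance = 1e-10)
})
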