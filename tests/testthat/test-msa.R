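test_that("alignment construction enforces its invariants", {
  expect_error(aa_msa(character(0)), "empty")
  expect_error(aa_msa(c(a = "ACD", b = "AC")), "same width")
  expect_error(aa_msa(c(a = "ACD", a = "ACD")), "unique")
  expect_error(aa_msa(c(a = "ACD"), query = 2), "query index")
  expect_error(aa_msa(c(a = "AXZ")), "illegal characters")
  m <- aa_msa(c(a = "AC.D", b = "AC-D"), query = "b")
  expect_equal(m$query, 2L)
  expect_identical(unname(m$mat[1, 3]), "-")   # '.' normalized
})

test_that("redundancy removal follows the greedy length/tie rules", {
  ## exact duplicates: later rows in input order discarded
  m <- make_msa(c(q = "ACDEF", a = "ACDEF", b = "ACDEF"))
  expect_identical(rownames(remove_redundant(m)$mat), "q")

  ## shorter (gappier) duplicate of a retained row is discarded
  m <- make_msa(c(q = "WWWWW", long = "ACDEY", short = "ACDE-"))
  expect_identical(rownames(remove_redundant(m)$mat), c("q", "long"))

  ## a longer later row replaces a shorter retained one
  m <- make_msa(c(q = "WWWWW", short = "ACDE-", long = "ACDEY"))
  expect_identical(rownames(remove_redundant(m)$mat), c("q", "long"))

  ## identity at 90% with threshold 0.95: both kept
  m <- make_msa(c(q = "ACDEFGHIKL", r = "ACDEFGHIKV"))
  expect_equal(nrow(remove_redundant(m, 0.95)$mat), 2L)

  ## the query is never discarded, even when shorter
  m <- make_msa(c(other = "ACDEF", q = "ACDE-"), query = 2)
  expect_true("q" %in% rownames(remove_redundant(m)$mat))
  expect_false("other" %in% rownames(remove_redundant(m)$mat))

  expect_error(remove_redundant(m, 0), "identity_threshold")
  expect_error(remove_redundant(m, 1.2), "identity_threshold")
})

test_that("redundancy removal is idempotent", {
  set.seed(11)
  for (rep in 1:5) {
    seqs <- vapply(1:8, function(i) {
      paste(sample(c(AA_ALPHABET20[1:4], "-"), 12, replace = TRUE), collapse = "")
    }, character(1))
    m <- make_msa(seqs)
    once <- remove_redundant(m)
    twice <- remove_redundant(once)
    expect_identical(once$mat, twice$mat)
  }
})

test_that("column filtering drops gappy columns and maps indices", {
  m <- make_msa(c(q = "A-CD", a = "A-CD", b = "C-DD"))
  out <- filter_columns(m, 0.99)
  expect_equal(ncol(out$msa$mat), 3L)             # all-gap column removed
  expect_equal(out$column_map, c(1L, NA, 2L, 3L))

  ## 50% gaps kept at threshold 0.99
  m2 <- make_msa(c(q = "AC", a = "-C"))
  expect_equal(ncol(filter_columns(m2, 0.99)$msa$mat), 2L)

  ## all columns removed
  m3 <- make_msa(c(q = "--", a = "--"))
  expect_error(filter_columns(m3, 0.99), "no informative columns")
})

test_that("variant strings parse and validate", {
  v <- parse_variant("A95E")
  expect_equal(v$wt, "A"); expect_equal(v$position, 95L); expect_equal(v$mut, "E")
  expect_equal(format(v), "A95E")
  expect_error(parse_variant("A95A"), "must differ")
  expect_error(parse_variant("B95E"), "not a standard")
  expect_error(parse_variant("95E"), "cannot parse")
  expect_error(parse_variant(wt = "A", position = 0, mut = "E"), ">= 1")
})

test_that("variants map to the correct alignment column", {
  m <- make_msa(c(q = "A-CD", r = "AACD"))
  expect_equal(map_variant_to_column(m, parse_variant(wt = "C", position = 2, mut = "A")), 3L)
  expect_error(map_variant_to_column(m, parse_variant(wt = "A", position = 5, mut = "C")),
               "beyond query length")
  expect_error(map_variant_to_column(m, parse_variant(wt = "W", position = 1, mut = "A")),
               "wild-type residue mismatch")
})

test_that("region selection extends left-first, clamps, and drops empty rows", {
  ## gap-free width 30, variant at column 15: alternating left-first gives 10-19
  m <- make_msa(c(q = strrep("A", 30), r = strrep("C", 30)))
  w <- select_region(m, 15)
  expect_equal(c(w$first, w$last), c(10L, 19L))

  ## gap-free width 8: clamped to the full alignment
  m8 <- make_msa(c(q = strrep("A", 8), r = strrep("C", 8)))
  w8 <- select_region(m8, 4)
  expect_equal(c(w8$first, w8$last), c(1L, 8L))

  ## all-gap row inside the window is removed
  m3 <- make_msa(c(q = "AAAAAAAAAAAA", r = "CCCCCCCCCCCC", s = "------------"))
  w3 <- select_region(m3, 6)
  expect_false("s" %in% rownames(w3$msa$mat))
  expect_true("q" %in% rownames(w3$msa$mat))

  expect_error(select_region(m3, 40), "out of range")
})

test_that("secondary extension passes query gaps only through clean columns", {
  ## query gapped on both flanks of a narrow core; other rows gap-free, so
  ## gap fraction (1/3) blocks the secondary extension at 0.10 but passes
  ## at a looser bound
  m <- make_msa(c(q = "---ACDEF---", r = "AAAAAAAAAAA", s = "CCCCCCCCCCC"))
  w <- select_region(m, 6, min_width = 10, extension_gap_fraction = 0.10)
  expect_equal(c(w$first, w$last), c(4L, 8L))   # blocked: only the query run
  w2 <- select_region(m, 6, min_width = 10, extension_gap_fraction = 0.5)
  expect_equal(w2$last - w2$first + 1L, 10L)
})

test_that("column filtering then region selection commutes through the index map", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- vapply(1:6, function(i) {
      paste(sample(c(AA_ALPHABET20[1:5], "-"), 20,
                   replace = TRUE, prob = c(rep(0.16, 5), 0.2)), collapse = "")
    }, character(1))
    ## ensure a gap-free query so variants are easy to place
    seqs[1] <- paste(sample(AA_ALPHABET20[1:5], 20, replace = TRUE), collapse = "")
    m <- make_msa(seqs)
    pos <- sample(5:15, 1)
    wt <- substr(seqs[1], pos, pos)
    mut <- setdiff(AA_ALPHABET20, wt)[1]
    v <- parse_variant(wt = wt, position = pos, mut = mut)
    col_orig <- map_variant_to_column(m, v)
    out <- filter_columns(m, 0.4)
    if (is.na(out$column_map[col_orig])) next
    col_via_map <- out$column_map[col_orig]
    col_direct <- map_variant_to_column(out$msa, parse_variant(
      wt = wt, position = sum(out$msa$mat[1, seq_len(col_via_map)] != "-"), mut = mut))
    expect_equal(col_via_map, col_direct)
  }
})

test_that("aligned FASTA and Stockholm round-trip through the readers", {
  m <- two_block_msa(2)
  fa <- tempfile(fileext = ".fasta")
  write_alignment(m, fa)
  back <- read_alignment(fa, query = "a1")
  expect_identical(back$mat, m$mat)
  expect_equal(back$query, 1L)

  sto <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "", "a1 ACDEF", "a2 ACDEF", "b1 WY.LM", "//"), sto)
  ms <- read_alignment(sto, query = "a1", format = "stockholm")
  expect_equal(dim(ms$mat), c(3L, 5L))
  expect_identical(unname(ms$mat["b1", 3]), "-")
})
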