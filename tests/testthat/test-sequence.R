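test_that("mutation notation parses, validates and round-trips", {
  m <- parse_mutations(c("G20R", "L100N"))
  expect_equal(m$wt, c("G", "L"))
  expect_equal(m$position, c(20L, 100L))
  expect_equal(m$mut, c("R", "N"))
  expect_equal(m$mutation, c("G20R", "L100N"))

  expect_error(parse_mutations("G20G"), "silent")
  expect_error(parse_mutations("20R"), "malformed")
  expect_error(parse_mutations("G-2R"), "malformed")
  expect_error(parse_mutations("G0R"), ">= 1")
  expect_error(parse_mutations("X20R"), "non-canonical")

  # exhaustive round trip: all ordered residue pairs at a spread of positions
  aa <- aa_alphabet()
  pairs <- expand.grid(wt = aa, mut = aa, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$wt != pairs$mut, ]
  for (pos in c(1L, 7L, 99L)) {
    tok <- paste0(pairs$wt, pos, pairs$mut)
    out <- parse_mutations(tok)
    expect_equal(out$mutation, tok)
    expect_equal(out$position, rep(pos, nrow(pairs)))
  }
})

test_that("apply_mutations edits exactly the stated sites and validates wt", {
  p <- parent_sequence("MGGA")
  expect_equal(apply_mutations(p, parse_mutations(character())), "MGGA")
  expect_equal(apply_mutations(p, "G3A"), "MGAA")
  expect_error(apply_mutations(p, "A3C"), "mismatch")
  expect_error(apply_mutations(p, c("G2A", "G2C")), "duplicate")
  expect_error(apply_mutations(p, "A9C"), "beyond")

  # diff is the exact inverse on random multi-mutants
  set.seed(3)
  long <- parent_sequence(random_seqs(1, 40))
  for (i in 1:20) {
    pos <- sort(sample(40, sample(1:5, 1)))
    chars <- strsplit(long$residues, "")[[1]]
    muts <- paste0(chars[pos], pos,
                   vapply(pos, function(q)
                     sample(setdiff(aa_alphabet(), chars[q]), 1), ""))
    s <- apply_mutations(long, muts)
    expect_equal(diff_to_mutations(long, s), paste(muts, collapse = ";"))
  }
  expect_error(diff_to_mutations(long, "ACD"), "length")
})

test_that("single-mutant enumeration is complete, exclusion-aware and ordered", {
  p10 <- parent_sequence(random_seqs(1, 10))
  cands <- enumerate_single_mutants(p10)
  expect_equal(nrow(cands), 190L)
  expect_false(any(cands$sequence == p10$residues))
  expect_equal(anyDuplicated(cands$sequence), 0L)

  # 19 * (L - E) over a grid of lengths and exclusion sizes
  set.seed(11)
  for (L in c(1, 2, 5, 13)) {
    p <- parent_sequence(random_seqs(1, L))
    for (E in unique(c(0, 1, L - 1))) {
      if (E >= L) next
      p$exclude <- sample(L, E)
      expect_equal(nrow(enumerate_single_mutants(p, with_sequence = FALSE)),
                   19L * (L - E))
    }
  }
  pAll <- parent_sequence("ACD", exclude = 1:3)
  expect_error(enumerate_single_mutants(pAll), "excluded")

  # deterministic order: position-major, mutant residue alphabetical
  p <- parent_sequence("AC")
  cands <- enumerate_single_mutants(p)
  expect_equal(cands$position, rep(1:2, each = 19))
  expect_equal(cands$mut[1:19], setdiff(aa_alphabet(), "A"))

  # length-1 parent: the 19 alternatives
  p1 <- parent_sequence("A")
  expect_equal(nrow(enumerate_single_mutants(p1)), 19L)
})

test_that("FASTA round-trips and strict mode rejects ambiguity codes", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(parent_sequence("MGGAVLKT", id = "s1"),
                   parent_sequence("ACDEFGHI", id = "s2")), tmp)
  back <- read_fasta(tmp)
  expect_length(back, 2)
  expect_equal(back[[1]]$id, "s1")
  expect_equal(back[[1]]$residues, "MGGAVLKT")
  expect_equal(back[[2]]$residues, "ACDEFGHI")

  writeLines(c(">bad", "ACDX", ">good", "ACDE"), tmp)
  expect_error(read_fasta(tmp), "non-canonical")
  expect_warning(kept <- read_fasta(tmp, strict = FALSE), "dropped")
  expect_length(kept, 1)
  expect_equal(kept[[1]]$id, "good")
})

test_that("variant tables parse mutation lists, diff sequences and validate", {
  parent <- parent_sequence(paste(rep("ACDEFGHIKL", 12), collapse = ""),
                            id = "p")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  seq_v2 <- apply_mutations(parent, "L100N")
  writeLines(c("id\tmutations\tsequence\trate\tatp_ratio",
               "v1\tC2G\t\t2.6\t4.2",
               paste0("v2\t\t", seq_v2, "\t1.0\t1.7"),
               paste0("wt\t\t", parent$residues, "\t0.9\t4.0")), tmp)
  d <- read_variant_table(tmp, parent)
  expect_equal(d$mutations, c("C2G", "L100N", ""))
  expect_equal(d$n_mutations, c(1L, 1L, 0L))
  expect_equal(d$rate, c(2.6, 1.0, 0.9))
  expect_equal(d$sequence[1], apply_mutations(parent, "C2G"))

  # wrong-length sequence
  writeLines(c("id\tsequence\trate\tatp_ratio", "v1\tACD\t1\t2"), tmp)
  expect_error(read_variant_table(tmp, parent), "length")
  # duplicate ids
  writeLines(c("id\tmutations\trate\tatp_ratio",
               "v1\tC2G\t1\t2", "v1\tC2A\t1\t2"), tmp)
  expect_error(read_variant_table(tmp, parent), "duplicate")
  # non-numeric target
  writeLines(c("id\tmutations\trate\tatp_ratio", "v1\tC2G\thigh\t2"), tmp)
  expect_error(read_variant_table(tmp, parent), "non-numeric")
})
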