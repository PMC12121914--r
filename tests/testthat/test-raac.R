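test_that("the 11-group scheme reproduces the canonical partition table", {
  op11 <- load_scheme("Op11")
  expect_identical(op11$size, 11L)
  expect_identical(op11$symbols,
                   c("G", "I", "F", "A", "L", "E", "P", "N", "H", "T", "V"))
  # the two symbol quirks: cysteine -> 'V', {I, V} -> 'I'
  expect_identical(unname(op11$map[["C"]]), "V")
  expect_identical(unname(op11$map[["I"]]), "I")
  expect_identical(unname(op11$map[["V"]]), "I")
  expect_identical(op11$groups[["E"]], c("E", "Q", "R", "K"))
  expect_identical(op11$groups[["F"]], c("F", "Y", "W"))
  # the 20 canonical residues map onto exactly 11 distinct symbols
  expect_identical(length(unique(op11$map)), 11L)
})

test_that("every registered scheme is a partition of the 20 residues", {
  for (nm in c("Op5", "Op8", "Op9", "Op11", "Op13", "Op20")) {
    sch <- load_scheme(nm)
    members <- sort(unname(unlist(sch$groups)))
    expect_identical(members, sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
                     info = nm)
    expect_identical(sch$size, length(sch$symbols), info = nm)
    expect_false(anyDuplicated(sch$symbols) > 0, info = nm)
  }
  expect_identical(load_scheme("Op5")$size, 5L)
  expect_identical(load_scheme("Op13")$size, 13L)
})

test_that("non-partition scheme files are rejected at load", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("A: ACDEFGHIKL", "B: LMNPQRSTVWY"), f)  # L twice
  expect_error(load_scheme(f), "more than one group")
  writeLines(c("A: ACDEFGHIK", "B: MNPQRSTVWY"), f)    # L missing
  expect_error(load_scheme(f), "not assigned")
  writeLines("A: ACDEFGHIKLMNPQRSTVWY*", f)
  expect_error(load_scheme(f), "malformed")
  expect_error(load_scheme("NoSuchScheme"), "neither")
})

test_that("sequence reduction is residue-wise and length-preserving", {
  expect_identical(as.character(reduce_sequence("ACDEFG", "Op11")), "AVNEFG")
  expect_identical(as.character(reduce_sequence("IVLM", "Op11")), "IILL")
  expect_identical(as.character(reduce_sequence("GGGG", "Op11")), "GGGG")
  expect_error(reduce_sequence("ACDXE", "Op11"), "position 4")
  set.seed(7)
  for (i in 1:10) {
    s <- random_canonical_seq(sample(10:80, 1))
    expect_identical(nchar(as.character(reduce_sequence(s, "Op11"))), nchar(s))
  }
})

test_that("sliding-window extraction yields the L - K + 1 ordered windows", {
  expect_identical(extract_kmers("ACDEFG", 3), c("ACD", "CDE", "DEF", "EFG"))
  expect_identical(extract_kmers("AAAA", 2), c("AA", "AA", "AA"))
  expect_warning(short <- extract_kmers("AB", 3), "shorter")
  expect_identical(short, character())
})

test_that("featurization matches the brute-force dictionary oracle exactly", {
  set.seed(11)
  for (scheme_name in c("Op11", "Op5", "Op20")) {
    sch <- load_scheme(scheme_name)
    for (k in 1:3) {
      for (rep in 1:7) {
        s <- random_canonical_seq(sample(k:50, 1))
        red <- as.character(reduce_sequence(s, sch))
        if (nchar(red) < k) next
        f <- kmer_features(red, sch, k)
        expected <- oracle_kmer_freq(red, colnames(f), k)
        expect_identical(unname(f[1, ]), unname(expected[colnames(f)]))
      }
    }
  }
})

test_that("frequencies are normalized and counts conserved", {
  set.seed(13)
  sch <- load_scheme("Op11")
  for (k in 1:3) {
    s <- random_canonical_seq(60)
    red <- reduce_sequence(s, sch)
    f <- kmer_features(red, sch, k)
    expect_identical(ncol(f), as.integer(11^k))
    expect_true(all(f >= 0))
    expect_lt(abs(sum(f) - 1), 1e-12)
    expect_identical(attr(f, "n_windows"), 60L - k + 1L)
  }
  f1 <- kmer_features("GGG", sch, 1)
  expect_identical(unname(f1[1, "G"]), 1)
  expect_identical(sum(f1), 1)
})

test_that("identity reduction at k = 1 equals amino-acid composition", {
  set.seed(17)
  s <- random_canonical_seq(100)
  f <- encode_records(s, "Op20", k = 1)
  comp <- table(factor(strsplit(s, "")[[1]],
                       levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_equal(unname(f[1, names(comp)]), unname(as.numeric(comp) / 100))
})

test_that("order sensitivity: k = 1 is permutation-invariant, k >= 2 is not", {
  set.seed(19)
  sch <- load_scheme("Op11")
  differs_at_2 <- 0
  for (i in 1:10) {
    s <- random_canonical_seq(50)
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    r1 <- reduce_sequence(s, sch); r2 <- reduce_sequence(perm, sch)
    expect_identical(kmer_features(r1, sch, 1), kmer_features(r2, sch, 1))
    if (!identical(kmer_features(r1, sch, 2)[1, ],
                   kmer_features(r2, sch, 2)[1, ]))
      differs_at_2 <- differs_at_2 + 1
  }
  expect_gt(differs_at_2, 7)
})

test_that("short sequences error in strict mode, zero-fill in lenient mode", {
  sch <- load_scheme("Op11")
  expect_error(kmer_features("AE", sch, 3), "shorter than k")
  expect_warning(f <- kmer_features(c("AE", "AVNEFG"), sch, 3,
                                    on_short = "zero"), "zero vectors")
  expect_identical(sum(f[1, ]), 0)
  expect_lt(abs(sum(f[2, ]) - 1), 1e-12)
})

test_that("k-mer index order is lexicographic over declared symbol order", {
  sch <- load_scheme("Op11")
  ab <- kmer_alphabet(sch, 2)
  expect_identical(length(ab), 121L)
  expect_identical(ab[1:3], c("GG", "GI", "GF"))
  expect_identical(ab[12], "IG")  # second block starts with second symbol
  expect_identical(ab[121], "VV")
})
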