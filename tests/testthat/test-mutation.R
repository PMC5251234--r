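test_that("mutant enumeration is complete, ordered and duplicate-free", {
  seq <- "GGGGAAAACC"
  muts <- enumerate_mutants(seq)
  expect_equal(nrow(muts), 30)                       # 3 per position
  expect_equal(muts$position, rep(1:10, each = 3))
  expect_true(all(muts$from != muts$to))
  expect_equal(anyDuplicated(muts[, c("position", "to")]), 0)
  # each mutant at Hamming distance exactly 1
  s <- strsplit(seq, "")[[1]]
  hd <- vapply(muts$sequence, function(m) {
    sum(strsplit(m, "")[[1]] != s)
  }, numeric(1), USE.NAMES = FALSE)
  expect_true(all(hd == 1))
  # substitutions listed in A < C < G < U order within a position
  expect_equal(muts$to[1:3], c("A", "C", "U"))       # from G
  expect_equal(muts$to[13:15], c("C", "G", "U"))     # from A
})

test_that("scan distances match the from-definition oracle", {
  rec <- rna_record("hp", "GGGGAAAACCCC")
  scan <- scan_mutations(rec)
  wild_db <- scan$record$structure
  for (r in c(1, 10, 36)) {
    row <- scan$mutants[r, ]
    s <- strsplit(rec$sequence, "")[[1]]
    s[row$position] <- row$to
    expect_equal(
      row$distance,
      1 - oracle_similarity(rec$sequence, wild_db,
                            paste(s, collapse = ""), row$structure),
      tolerance = 1e-9
    )
  }
})

test_that("stem-disrupting mutations outrank structure-preserving ones", {
  scan <- scan_mutations(rna_record("hp", "GGGGAAAACCCC"))
  wild_db <- scan$record$structure          # ((((....))))
  m <- scan$mutants
  preserved <- m[m$structure == wild_db & m$position %in% 5:8, ]
  stem <- m[m$structure != wild_db & !(m$position %in% 5:8), ]
  expect_gt(nrow(preserved), 0)
  expect_gt(nrow(stem), 0)
  # some stem-disrupting substitution beats every pairing-preserving one
  expect_gt(max(stem$distance), max(preserved$distance))
})

test_that("profile, ranking and histogram conserve the 3N mutants", {
  set.seed(13)
  rec <- random_structured_record("r", 20)
  scan <- scan_mutations(rec)
  expect_equal(nrow(scan$mutants), 60)
  expect_equal(sum(scan$histogram$counts), 60)
  expect_equal(nrow(scan$profile), 20)
  # profile entries are the per-position maxima of the ranked table
  agg <- tapply(scan$mutants$distance, scan$mutants$position, max)
  expect_equal(scan$profile$max_distance, as.vector(agg[as.character(1:20)]))
  # the reported maximal mutant attains the profile maximum
  expect_equal(scan$maximal$distance, max(scan$profile$max_distance))
  expect_true(!is.unsorted(rev(scan$mutants$distance)))
})

test_that("maximal-mutant ties break by position then A<C<G<U", {
  # all-A sequence: every mutant folds unpaired, scores depend on base only;
  # many exact ties, so the tie-break is exercised for real
  scan <- scan_mutations(rna_record("flat", strrep("A", 12)))
  top <- scan$mutants[scan$mutants$distance == scan$maximal$distance, ]
  expect_equal(scan$maximal$position, min(top$position))
  first_pos <- top[top$position == scan$maximal$position, ]
  expect_equal(scan$maximal$to,
               sort(first_pos$to)[1])
})

test_that("scans are deterministic and exportable", {
  rec <- rna_record("hp", "GGGGAAAACCCC")
  s1 <- scan_mutations(rec)
  s2 <- scan_mutations(rec)
  s1$cfg <- s2$cfg <- NULL  # config carries no state but holds a call env
  expect_identical(s1[c("mutants", "profile", "histogram", "maximal")],
                   s2[c("mutants", "profile", "histogram", "maximal")])
  dir <- withr::local_tempdir()
  paths <- write_scan_tsv(scan_mutations(rec), dir)
  expect_true(all(file.exists(paths)))
  mut <- utils::read.delim(paths[1])
  expect_equal(nrow(mut), 36)
})

test_that("histogram bins are uniform and conserve counts", {
  h <- distance_histogram(rep(0.5, 12), bins = 20)
  expect_equal(sum(h$counts), 12)
  expect_equal(sum(h$counts > 0), 1)                 # single occupied bin
  h1 <- distance_histogram(runif(30), bins = 1)
  expect_equal(h1$counts, 30)
  h20 <- distance_histogram(seq(0, 1, length.out = 21), bins = 20)
  expect_equal(sum(h20$counts), 21)
  expect_equal(diff(h20$edges), rep(0.05, 20))
})

test_that("short records are rejected by the scan entry point", {
  expect_error(scan_mutations(rna_record("s", "GGGAAACCC")),
               "minimal length is 10")
})
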