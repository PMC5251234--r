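test_that("configuration validates and normalises its inputs", {
  cfg <- tvc_config()
  expect_equal(cfg$levels, 4)
  expect_equal(cfg$wavelet, "haar")
  expect_equal(cfg$weights, rep(1 / 5, 5))
  expect_equal(sum(tvc_config(levels = 3, weights = c(4, 2, 2, 2))$weights), 1)
  expect_error(tvc_config(levels = 0))
  expect_error(tvc_config(weights = c(1, 1)))       # wrong length
  expect_error(tvc_config(wavelet = "sym8"))
})

test_that("resampling is linear interpolation with preserved endpoints", {
  x <- c(0.3, -1, 2, 0.5)
  expect_identical(resample_signal(x, 4), x)
  expect_equal(resample_signal(rep(2.5, 5), 9), rep(2.5, 9))
  expect_equal(resample_signal(c(0, 1, 2, 3), 7),
               c(0, 0.5, 1, 1.5, 2, 2.5, 3))
  set.seed(8)
  y <- rnorm(10)
  out <- resample_signal(y, 17)
  expect_equal(out[1], y[1])
  expect_equal(out[17], y[10])
  expect_error(resample_signal(1, 4))
})

test_that("the wavelet pyramid matches closed forms and inverts exactly", {
  d <- wavelet_decompose(c(1, -1), tvc_config(levels = 1))
  expect_equal(d$approx, 0)
  expect_equal(d$details[[1]], sqrt(2))

  # constants have no detail at any level
  d <- wavelet_decompose(rep(3.7, 32), tvc_config())
  expect_true(all(abs(unlist(d$details)) == 0))

  set.seed(9)
  for (wavelet in c("haar", "d4")) {
    for (m in c(16, 64, 256)) {
      x <- rnorm(m)
      dec <- wavelet_decompose(x, tvc_config(levels = 4, wavelet = wavelet))
      expect_equal(lengths(dec$details), m / 2^(1:4), ignore_attr = TRUE)
      expect_length(dec$approx, m / 2^4)
      expect_lt(max(abs(wavelet_reconstruct(dec) - x)), 1e-9)
    }
  }

  # Haar coefficients equal the explicit orthonormal matrix product
  x <- rnorm(32)
  dec <- wavelet_decompose(x, tvc_config(levels = 2))
  st1 <- oracle_haar_step(x)
  st2 <- oracle_haar_step(st1$a)
  expect_equal(dec$details[[1]], st1$d)
  expect_equal(dec$details[[2]], st2$d)
  expect_equal(dec$approx, st2$a)

  expect_warning(wavelet_decompose(rnorm(8), tvc_config(levels = 6)),
                 "L reduced")
})

test_that("multi-scale similarity agrees with the from-definition oracle", {
  set.seed(1)
  for (k in 1:20) {
    sa <- random_rna_seq(sample(10:64, 1))
    sb <- random_rna_seq(sample(10:64, 1))
    da <- fold_nussinov(sa)
    db <- fold_nussinov(sb)
    got <- multiscale_similarity(tv_curve(sa, da), tv_curve(sb, db))
    expect_lt(abs(got - oracle_similarity(sa, da, sb, db)), 1e-9)
  }
})

test_that("similarity is an exact symmetric identity-respecting score", {
  set.seed(2)
  for (k in 1:10) {
    a <- tv_curve(random_structured_record("a", sample(10:50, 1)))
    b <- tv_curve(random_structured_record("b", sample(10:50, 1)))
    sab <- multiscale_similarity(a, b)
    expect_identical(sab, multiscale_similarity(b, a))
    expect_gte(sab, -1 - 1e-12)
    expect_lte(sab, 1 + 1e-12)
    expect_equal(multiscale_similarity(a, a), 1)
  }
})

test_that("similarity is invariant under rescaling of the weights", {
  a <- tv_curve(random_structured_record("a", 30))
  b <- tv_curve(random_structured_record("b", 41))
  s1 <- multiscale_similarity(a, b, tvc_config(weights = c(1, 1, 1, 1, 1)))
  s2 <- multiscale_similarity(a, b, tvc_config(weights = c(7, 7, 7, 7, 7)))
  expect_equal(s1, s2)
})

test_that("degenerate constant signals follow the zero-variance convention", {
  allA <- tv_curve(rna_record("a", strrep("A", 12), strrep(".", 12)))
  allA2 <- tv_curve(rna_record("a2", strrep("A", 12), strrep(".", 12)))
  # identical monotone curves: every level matches, including constant ones
  expect_equal(multiscale_similarity(allA, allA2), 1)
  allC <- tv_curve(rna_record("c", strrep("C", 12), strrep(".", 12)))
  s <- multiscale_similarity(allA, allC)
  # detail levels are constant-and-unequal or zero: correlations 0 or +/-1
  expect_true(is.finite(s))
  expect_equal(similarity_to_distance(1), 0)
  expect_equal(similarity_to_distance(0.3), 0.7)
  expect_equal(similarity_to_distance(-1), 2)
})

test_that("a local symbol perturbation moves fine details more than the
           approximation", {
  set.seed(2)
  seq <- random_rna_seq(64)
  db <- fold_nussinov(seq)
  s <- strsplit(seq, "")[[1]]
  # swap G<->C at an unpaired site: same step-sum, so the change is purely
  # local and should surface at the fine scales, not the coarse one
  unp <- which(strsplit(db, "")[[1]] == "." & s %in% c("G", "C"))
  i <- unp[ceiling(length(unp) / 2)]
  s[i] <- if (s[i] == "G") "C" else "G"
  cfg <- tvc_config()
  a <- tv_curve(seq, db)
  b <- tv_curve(paste(s, collapse = ""), db)
  da <- wavelet_decompose(resample_signal(a$points[-1, "y"], 256), cfg)
  dbv <- wavelet_decompose(resample_signal(b$points[-1, "y"], 256), cfg)
  drho_approx <- abs(1 - stats::cor(da$approx, dbv$approx))
  drho_fine <- abs(1 - stats::cor(da$details[[1]], dbv$details[[1]]))
  expect_gt(drho_fine, drho_approx)
})

test_that("record-level distance wraps folding, encoding and scoring", {
  ra <- rna_record("a", "GGGGAAAACCCC")
  rb <- rna_record("b", "GGGGAAAACCCC", "((((....))))")
  # nussinov agrees with the provided structure here, so distance is 0
  expect_equal(tvc_distance(ra, rb), 0)
  rc <- rna_record("c", "ACACACACACAC")
  expect_gt(tvc_distance(ra, rc), 0)
})
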