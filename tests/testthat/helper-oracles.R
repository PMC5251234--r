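# Independent from-definition oracles used to cross-check the package.
# Everything here is written straight from the method definitions and shares
# no code path with the package internals.

ORACLE_STEP_TABLE <- list(
  "A"  = c( 1,  1,  1), "A'" = c(-1, -1,  1),
  "U"  = c( 1, -1,  1), "U'" = c(-1,  1,  1),
  "G"  = c( 1, -1, -1), "G'" = c( 1,  1, -1),
  "C"  = c(-1,  1, -1), "C'" = c(-1, -1, -1)
)

oracle_paired_flags <- function(db) {
  chars <- strsplit(db, "")[[1]]
  paired <- logical(length(chars))
  open <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") open <- c(open, k)
    if (chars[k] == ")") {
      paired[c(open[length(open)], k)] <- TRUE
      open <- open[-length(open)]
    }
  }
  paired
}

oracle_curve_signal <- function(seq, db, kind = "cumulative") {
  bases <- strsplit(seq, "")[[1]]
  paired <- oracle_paired_flags(db)
  syms <- ifelse(paired, paste0(bases, "'"), bases)
  steps <- unlist(ORACLE_STEP_TABLE[syms], use.names = FALSE)
  if (kind == "steps") steps else cumsum(steps)
}

# linear interpolation on a uniform [0,1] grid, written out index by index
oracle_resample <- function(x, m) {
  n <- length(x)
  if (n == m) return(x)
  out <- numeric(m)
  for (t in seq_len(m)) {
    pos <- (t - 1) / (m - 1) * (n - 1) + 1
    lo <- floor(pos)
    if (lo >= n) { out[t] <- x[n]; next }
    frac <- pos - lo
    out[t] <- x[lo] * (1 - frac) + x[lo + 1] * frac
  }
  out
}

# one orthonormal Haar analysis step as an explicit matrix product
oracle_haar_step <- function(x) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (k in seq_len(n / 2)) {
    H[k, 2 * k - 1] <- 1 / sqrt(2); H[k, 2 * k] <- 1 / sqrt(2)
    H[n / 2 + k, 2 * k - 1] <- 1 / sqrt(2); H[n / 2 + k, 2 * k] <- -1 / sqrt(2)
  }
  y <- as.vector(H %*% x)
  list(a = y[seq_len(n / 2)], d = y[n / 2 + seq_len(n / 2)])
}

oracle_pearson <- function(u, v) {
  cu <- length(u) < 2 || stats::sd(u) == 0
  cv <- length(v) < 2 || stats::sd(v) == 0
  if (cu || cv) return(if (cu && cv && isTRUE(all.equal(u, v))) 1 else 0)
  stats::cor(u, v)
}

# straight-line multi-scale similarity: encode, resample to the common
# dyadic length, Haar pyramid via matrix products, weighted Pearson sum
oracle_similarity <- function(seq_a, db_a, seq_b, db_b, L = 4,
                              kind = "cumulative") {
  sa <- oracle_curve_signal(seq_a, db_a, kind)
  sb <- oracle_curve_signal(seq_b, db_b, kind)
  m <- 2^ceiling(log2(max(length(sa), length(sb))))
  xa <- oracle_resample(sa, m)
  xb <- oracle_resample(sb, m)
  w <- rep(1 / (L + 1), L + 1)
  rho <- numeric(L + 1)
  for (j in seq_len(L)) {
    st_a <- oracle_haar_step(xa)
    st_b <- oracle_haar_step(xb)
    rho[j + 1] <- oracle_pearson(st_a$d, st_b$d)
    xa <- st_a$a
    xb <- st_b$a
  }
  rho[1] <- oracle_pearson(xa, xb)
  sum(w * rho)
}

# exhaustive enumeration of every nested, loop-respecting pairing; returns
# the maximum pair count (no memoisation — a true brute-force search)
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  ok <- function(a, b) paste0(s[a], s[b]) %in%
    c("AU", "UA", "GC", "CG", "GU", "UG")
  best <- function(lo, hi) {
    if (hi - lo < min_loop + 1) return(0)
    b <- best(lo + 1, hi) # lo unpaired
    for (k in (lo + min_loop + 1):hi) {
      if (ok(lo, k)) {
        b <- max(b, 1 + best(lo + 1, k - 1) + if (k < hi) best(k + 1, hi) else 0)
      }
    }
    b
  }
  if (length(s) < min_loop + 2) 0 else best(1, length(s))
}

# UPGMA by literal re-averaging: cluster distances recomputed every round
# as plain means of all cross-cluster leaf distances in the original matrix
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  labs <- rownames(D)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        lab <- sort(c(min(labs[clusters[[i]]]), min(labs[clusters[[j]]])))
        if (is.null(best) || d < best$d ||
            (d == best$d && (lab[1] < best$lab[1] ||
                             (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = d, lab = lab)
        }
      }
    }
    coph[clusters[[best$i]], clusters[[best$j]]] <- best$d
    coph[clusters[[best$j]], clusters[[best$i]]] <- best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# random ultrametric matrix from a random merge sequence with growing heights
random_ultrametric <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  clusters <- lapply(seq_len(n), identity)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  h <- 0
  while (length(clusters) > 1) {
    h <- h + stats::runif(1, 0.1, 1)
    pick <- sample(length(clusters), 2)
    a <- clusters[[pick[1]]]
    b <- clusters[[pick[2]]]
    D[a, b] <- h
    D[b, a] <- h
    clusters[[pick[1]]] <- c(a, b)
    clusters[[pick[2]]] <- NULL
  }
  D
}

random_symmetric_matrix <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- stats::runif(n * (n - 1) / 2, 0.05, 2)
  D[lower.tri(D)] <- vals
  D <- D + t(D)
  D
}

random_rna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_structured_record <- function(id, len) {
  seq <- random_rna_seq(len)
  rna_record(id, seq, fold_nussinov(seq))
}

random_characteristic_string <- function(len) {
  sample(names(tv_step_table), len, replace = TRUE)
}
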