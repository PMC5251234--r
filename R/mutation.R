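RNA_BASES <- c("A", "C", "G", "U")

#' Enumerate all single-point mutants of a sequence
#'
#' Each of the N positions admits exactly three substitutions, giving 3N
#' mutants at Hamming distance 1 from the input. Ordering is position
#' ascending, substitution in `A < C < G < U` order.
#'
#' @param seq RNA sequence string.
#' @return Data frame with columns `position`, `from`, `to`, `sequence`
#'   (3N rows).
#' @examples
#' nrow(enumerate_mutants("GGGGAAAACCCC"))  # 36
#' @export
enumerate_mutants <- function(seq) {
  s <- strsplit(normalize_sequence(seq), "")[[1]]
  n <- length(s)
  rows <- vector("list", 3L * n)
  k <- 0L
  for (i in seq_len(n)) {
    for (to in setdiff(RNA_BASES, s[i])) {
      k <- k + 1L
      mut <- s
      mut[i] <- to
      rows[[k]] <- data.frame(position = i, from = s[i], to = to,
                              sequence = paste(mut, collapse = ""),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Scan all single-point mutants for structural impact
#'
#' Folds the wild type if no structure is provided, then enumerates all 3N
#' single-point mutants, re-folds each one with the same backend (mutants
#' never inherit the wild-type structure), and scores the structural
#' distance `1 - multiscale_similarity(wild, mutant)` for each. The result
#' carries the full mutant table ranked by distance (descending; ties by
#' position, then `A < C < G < U`), the per-position deleteriousness profile
#' (the maximum distance over the three substitutions at each position,
#' with the argmax substitution), a histogram of all 3N distances, and the
#' single maximal mutant.
#'
#' @param rec An [rna_record()], length >= `min_len`.
#' @param backend A [fold_backend()].
#' @param cfg A [tvc_config()].
#' @param bins Number of histogram bins.
#' @param min_len Minimal accepted sequence length.
#' @return Object of class `tvc_scan`: list with `record` (wild type, with
#'   structure), `mutants` (ranked data frame: `position`, `from`, `to`,
#'   `distance`, `structure`), `profile` (data frame: `position`,
#'   `max_distance`, `to`), `histogram` (list `edges`, `counts`), `maximal`
#'   (one-row data frame), `cfg`, `backend_name`.
#' @export
scan_mutations <- function(rec, backend = fold_backend("nussinov"),
                           cfg = tvc_config(), bins = 20L, min_len = 10L) {
  rec <- validate_record(rec, min_len)
  rec <- ensure_structure(rec, backend)
  wild <- tv_curve(rec)
  muts <- enumerate_mutants(rec$sequence)
  muts$structure <- vapply(muts$sequence, backend$fold, "", USE.NAMES = FALSE)
  muts$distance <- vapply(seq_len(nrow(muts)), function(r) {
    cv <- tv_curve(muts$sequence[r], muts$structure[r])
    similarity_to_distance(multiscale_similarity(wild, cv, cfg))
  }, numeric(1))

  # per-position maxima; within-position ties resolved by A < C < G < U
  profile <- do.call(rbind, lapply(split(muts, muts$position), function(g) {
    g <- g[order(-g$distance, match(g$to, RNA_BASES)), ]
    data.frame(position = g$position[1], max_distance = g$distance[1],
               to = g$to[1], stringsAsFactors = FALSE)
  }))
  profile <- profile[order(profile$position), ]
  rownames(profile) <- NULL

  ranked <- muts[order(-muts$distance, muts$position,
                       match(muts$to, RNA_BASES)),
                 c("position", "from", "to", "distance", "structure")]
  rownames(ranked) <- NULL

  structure(
    list(record = rec, mutants = ranked, profile = profile,
         histogram = distance_histogram(muts$distance, bins),
         maximal = ranked[1L, ], cfg = cfg, backend_name = backend$name),
    class = "tvc_scan"
  )
}

#' Histogram of mutant distances
#'
#' Uniform bins over `[0, max(distances, eps)]`; counts sum to the number of
#' distances.
#'
#' @param distances Numeric vector of distances (>= 0).
#' @param bins Number of bins (>= 1).
#' @return List with `edges` (length `bins + 1`) and `counts` (length
#'   `bins`).
#' @export
distance_histogram <- function(distances, bins = 20L) {
  stopifnot(bins >= 1L, all(distances >= -1e-12))
  upper <- max(distances, 1e-9)
  edges <- seq(0, upper, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(distances, edges, rightmost.closed = TRUE),
                   1L), bins)
  list(edges = edges, counts = tabulate(idx, nbins = bins))
}

#' @export
print.tvc_scan <- function(x, ...) {
  cat(sprintf("Mutation scan of '%s' (%d nt, backend %s): %d mutants\n",
              x$record$id, x$record$length, x$backend_name, nrow(x$mutants)))
  m <- x$maximal
  cat(sprintf("  maximal mutant: %s%d%s, distance %.6f\n",
              m$from, m$position, m$to, m$distance))
  invisible(x)
}

#' Plot a mutation scan
#'
#' Two panels: the per-position deleteriousness profile and the histogram of
#' all mutant distances.
#'
#' @param x A `tvc_scan`.
#' @param ... Ignored.
#' @export
plot.tvc_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$profile$position, x$profile$max_distance, type = "h",
                 xlab = "position", ylab = "max structural distance",
                 main = "Deleteriousness profile")
  h <- x$histogram
  mids <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
  graphics::plot(mids, h$counts, type = "h", xlab = "distance",
                 ylab = "count", main = "Mutant distances")
  invisible(x)
}

#' Write mutation-scan outputs as TSV
#'
#' Writes `mutants.tsv` (ranked table), `profile.tsv` and `histogram.tsv`
#' into `dir`.
#'
#' @param scan A `tvc_scan`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scan_tsv <- function(scan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("mutants.tsv", "profile.tsv", "histogram.tsv"))
  mut <- scan$mutants
  mut$distance <- sprintf("%.6f", mut$distance)
  utils::write.table(mut, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prof <- scan$profile
  prof$max_distance <- sprintf("%.6f", prof$max_distance)
  utils::write.table(prof, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  h <- scan$histogram
  hist_df <- data.frame(bin_low = h$edges[-length(h$edges)],
                        bin_high = h$edges[-1], count = h$counts)
  utils::write.table(hist_df, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
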