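with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_rna <- function(length) {
  paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
}

mutate_sequence <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) s[i] <- sample(setdiff(RNA_BASES, s[i]), 1L)
  paste(s, collapse = "")
}

#' Generate planted synthetic RNA sequence families
#'
#' For each family a random ancestor sequence is drawn and folded with the
#' deterministic fallback backend; members are then derived by independent
#' per-site substitutions at `mutation_rate` (every hit site changes to one
#' of the three other bases) and re-folded. Records are labelled
#' `family<i>_member<j>` and carry their predicted structures, so downstream
#' steps need no further folding. Fully deterministic under `seed`; the
#' global RNG state is restored afterwards.
#'
#' This emulates sets of structurally related RNA families at a chosen
#' divergence; it does not emulate indels, covariation-preserving
#' (compensatory) mutations, or thermodynamic folding.
#'
#' @param n_families Number of families.
#' @param members Members per family.
#' @param length Sequence length (nt).
#' @param mutation_rate Per-site substitution probability in (0, 1).
#' @param seed Integer seed.
#' @param path Optional output path; the records are written there in the
#'   extended-FASTA dialect.
#' @param backend A [fold_backend()] used to fold ancestors and members.
#' @return List of [rna_record()] objects (invisibly written to `path` if
#'   given), with a `family` attribute giving the planted family index per
#'   record.
#' @examples
#' recs <- generate_synthetic(2, 3, 40, 0.05, seed = 1)
#' length(recs)  # 6
#' @export
generate_synthetic <- function(n_families, members, length, mutation_rate,
                               seed, path = NULL,
                               backend = fold_backend("nussinov")) {
  stopifnot(n_families >= 1L, members >= 1L, length >= 1L,
            mutation_rate > 0, mutation_rate < 1)
  records <- with_seed(seed, {
    out <- list()
    for (f in seq_len(n_families)) {
      ancestor <- random_rna(length)
      for (m in seq_len(members)) {
        seq <- mutate_sequence(ancestor, mutation_rate)
        out[[base::length(out) + 1L]] <- rna_record(
          sprintf("family%d_member%d", f, m), seq, backend$fold(seq)
        )
      }
    }
    out
  })
  attr(records, "family") <- rep(seq_len(n_families), each = members)
  if (!is.null(path)) write_rna_fasta(records, path)
  invisible(records)
}
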