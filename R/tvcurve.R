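#' The eight characteristic symbols and their step triples
#'
#' The characteristic representation writes an RNA with its secondary
#' structure over eight symbols: `A,C,G,U` for unpaired bases and the primed
#' `A',C',G',U'` for the same bases when hydrogen-bonded. Each symbol maps to
#' a triple of vertical steps in \{-1,+1\}; concatenating the triples and
#' cumulatively summing them yields the TV-curve.
#'
#' The mapping is a bijection over the eight symbols:
#' `A  -> (+1,+1,+1)`, `A' -> (-1,-1,+1)`,
#' `U  -> (+1,-1,+1)`, `U' -> (-1,+1,+1)`,
#' `G  -> (+1,-1,-1)`, `G' -> (+1,+1,-1)`,
#' `C  -> (-1,+1,-1)`, `C' -> (-1,-1,-1)`.
#' `C'` takes the one sign pattern left unused by the other seven symbols,
#' which is what makes the encoding invertible (see the methods vignette for
#' the discussion of this choice).
#'
#' @format A named list of 8 integer triples, names `A, A', U, U', G, G',
#'   C, C'`.
#' @export
tv_step_table <- list(
  "A"  = c( 1L,  1L,  1L),
  "A'" = c(-1L, -1L,  1L),
  "U"  = c( 1L, -1L,  1L),
  "U'" = c(-1L,  1L,  1L),
  "G"  = c( 1L, -1L, -1L),
  "G'" = c( 1L,  1L, -1L),
  "C"  = c(-1L,  1L, -1L),
  "C'" = c(-1L, -1L, -1L)
)

#' Characteristic representation of a structured RNA
#'
#' Position `i` becomes the primed symbol `base'` if `i` takes part in a base
#' pair, and the plain `base` otherwise.
#'
#' @param seq RNA sequence string.
#' @param structure Dot-bracket string of equal length (or a parsed structure
#'   from [parse_dotbracket()]).
#' @return Character vector of symbols from `names(tv_step_table)`.
#' @examples
#' characteristic_representation("GAAAC", "(...)")  # "G'" "A" "A" "A" "C'"
#' @export
characteristic_representation <- function(seq, structure) {
  bases <- strsplit(normalize_sequence(seq), "")[[1]]
  if (is.character(structure)) structure <- parse_dotbracket(structure)
  if (nchar(structure$dotbracket) != length(bases)) {
    stop(sprintf("structure length %d does not match sequence length %d",
                 nchar(structure$dotbracket), length(bases)), call. = FALSE)
  }
  paired <- logical(length(bases))
  paired[as.vector(structure$pairs)] <- TRUE
  ifelse(paired, paste0(bases, "'"), bases)
}

#' Encode an RNA as a triple-vector curve
#'
#' Concatenates the step triples of the characteristic symbols and cumulates
#' them from the origin: a record of length N yields 3N steps in \{-1,+1\}
#' and 3N+1 curve points `(k, y_k)` with `y_0 = 0`.
#'
#' @param rec An [rna_record()] carrying a structure, or a sequence string
#'   (then `structure` must be given).
#' @param structure Dot-bracket string, required when `rec` is a bare
#'   sequence and optional otherwise.
#' @param backend A [fold_backend()] used only if no structure is available.
#' @return An object of class `tvcurve`: list with `id`, `symbols` (length
#'   N), `steps` (integer, length 3N), `points` (matrix `(3N+1) x 2`, columns
#'   `x`, `y`) and `n`.
#' @examples
#' cv <- tv_curve(rna_record("hp", "GAAAC", "(...)"))
#' cv$points[nrow(cv$points), ]   # endpoint (15, 7)
#' @export
tv_curve <- function(rec, structure = NULL, backend = fold_backend("nussinov")) {
  if (is.character(rec)) {
    rec <- rna_record("<sequence>", rec, structure)
  } else if (!is.null(structure)) {
    rec <- rna_record(rec$id, rec$sequence, structure)
  }
  stopifnot(inherits(rec, "rna_record"))
  rec <- ensure_structure(rec, backend)
  syms <- characteristic_representation(rec$sequence, rec$structure)
  steps <- unlist(tv_step_table[syms], use.names = FALSE)
  y <- c(0L, cumsum(steps))
  structure(
    list(id = rec$id, symbols = syms, steps = steps,
         points = cbind(x = 0L:(length(steps)), y = y), n = rec$length),
    class = "tvcurve"
  )
}

#' Decode a step signal back to characteristic symbols
#'
#' Inverse of the encoding: consumes the +/-1 step signal three at a time and
#' looks each triple up in the (bijective) step table.
#'
#' @param steps Integer/numeric vector of +/-1 values, length divisible by 3.
#' @return Character vector of characteristic symbols.
#' @export
decode_steps <- function(steps) {
  stopifnot(length(steps) %% 3 == 0, all(steps %in% c(-1, 1)))
  keys <- vapply(tv_step_table, paste, "", collapse = ",")
  mat <- matrix(as.integer(steps), nrow = 3)
  triples <- apply(mat, 2, paste, collapse = ",")
  idx <- match(triples, keys)
  if (anyNA(idx)) stop("step triple not in the mapping table", call. = FALSE) # nocov
  names(tv_step_table)[idx]
}

#' @export
print.tvcurve <- function(x, ...) {
  endpoint <- x$points[nrow(x$points), ]
  cat(sprintf("TV-curve '%s': %d nt, %d steps, endpoint (%d, %d)\n",
              x$id, x$n, length(x$steps), endpoint[1], endpoint[2]))
  cat("  symbols:", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

#' Plot a TV-curve
#'
#' Draws the cumulative curve as a line through its `3N+1` points.
#'
#' @param x A `tvcurve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tvcurve <- function(x, ...) {
  graphics::plot(x$points[, "x"], x$points[, "y"], type = "l",
                 xlab = "step index", ylab = "cumulative value",
                 main = sprintf("TV-curve: %s", x$id), ...)
  invisible(x)
}

#' Export curve points as TSV
#'
#' @param curve A `tvcurve`.
#' @param path Output path; `NULL` returns the data frame only.
#' @return Invisibly, a data frame with columns `x`, `y`.
#' @export
write_tvcurve_tsv <- function(curve, path = NULL) {
  df <- as.data.frame(curve$points)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
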