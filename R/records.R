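#' RNA record
#'
#' Bundles one RNA: an identifier, an uppercase sequence over `A,C,G,U`
#' (input `T`/`t` is silently normalised to `U`, tolerating DNA-alphabet
#' input), and an optional dot-bracket secondary structure of equal length.
#'
#' @param id Character label for the record.
#' @param sequence RNA (or DNA) sequence string; case-insensitive.
#' @param structure Optional dot-bracket string over `.`, `(`, `)` whose
#'   length equals `nchar(sequence)`. A trailing RNAfold-style free-energy
#'   annotation such as `" (-1.20)"` is stripped before validation.
#' @return An object of class `rna_record`: a list with elements `id`,
#'   `sequence`, `structure` (`NULL` if absent) and `length`.
#' @examples
#' rna_record("hairpin", "GGGGAAAACCCC", "((((....))))")
#' rna_record("dna-input", "GGGTAAACCC")   # T becomes U
#' @export
rna_record <- function(id, sequence, structure = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- normalize_sequence(sequence, id)
  if (!is.null(structure)) {
    structure <- strip_energy_annotation(structure)
    if (nchar(structure) != nchar(seq)) {
      stop(sprintf(
        "record '%s': structure length %d does not match sequence length %d",
        id, nchar(structure), nchar(seq)
      ), call. = FALSE)
    }
    parse_dotbracket(structure) # raises on imbalance / foreign characters
  }
  structure(
    list(id = id, sequence = seq, structure = structure,
         length = nchar(seq)),
    class = "rna_record"
  )
}

normalize_sequence <- function(sequence, id = "<record>") {
  seq <- toupper(sequence)
  seq <- chartr("T", "U", seq)
  bad <- gsub("[ACGU]", "", seq)
  if (nzchar(bad)) {
    stop(sprintf("record '%s': invalid sequence character(s) '%s'",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = "")),
         call. = FALSE)
  }
  seq
}

strip_energy_annotation <- function(line) {
  sub("\\s+\\(\\s*-?[0-9]+(\\.[0-9]+)?\\s*\\)\\s*$", "", line)
}

is_structure_line <- function(line) {
  core <- strip_energy_annotation(line)
  nzchar(core) && grepl("^[.()]+$", core)
}

#' @export
print.rna_record <- function(x, ...) {
  cat(sprintf("RNA record '%s' (%d nt)\n", x$id, x$length))
  cat(" ", x$sequence, "\n")
  if (!is.null(x$structure)) cat(" ", x$structure, "\n")
  invisible(x)
}

#' Validate an RNA record for the comparison entry points
#'
#' Comparison, mutation-scan and phylogeny entry points require sequences of
#' at least `min_len` nucleotides (default 10). Encoding primitives accept
#' any length, so unit-level work on tiny strings is unaffected.
#'
#' @param rec An [rna_record()].
#' @param min_len Minimal accepted sequence length.
#' @return `rec`, unchanged, if valid; otherwise an error naming the record.
#' @export
validate_record <- function(rec, min_len = 10L) {
  stopifnot(inherits(rec, "rna_record"))
  if (rec$length < min_len) {
    stop(sprintf("record '%s' has length %d; the minimal length is %d",
                 rec$id, rec$length, min_len), call. = FALSE)
  }
  if (!is.null(rec$structure)) parse_dotbracket(rec$structure)
  rec
}

#' Parse a dot-bracket string into base pairs
#'
#' Standard stack semantics: `(` opens a pair, `)` closes the most recent
#' open one, `.` is unpaired. Only the plain single-bracket dialect is
#' supported; pseudoknot brackets (`[`, `{`, ...) are rejected.
#'
#' @param db Dot-bracket string.
#' @return A list with `dotbracket` (the input) and `pairs`, an integer
#'   matrix with columns `i`, `j` (1-based, `i < j`), one row per pair,
#'   ordered by `i`.
#' @examples
#' parse_dotbracket("((..))")$pairs
#' @export
parse_dotbracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "")[[1]]
  foreign <- setdiff(unique(chars), c(".", "(", ")"))
  if (length(foreign)) {
    if (any(foreign %in% c("[", "]", "{", "}", "<", ">"))) {
      stop("pseudoknot bracket(s) are not supported: ",
           paste(foreign, collapse = ""), call. = FALSE)
    }
    stop("invalid dot-bracket character(s): ",
         paste(foreign, collapse = ""), call. = FALSE)
  }
  open <- integer(0)
  i_col <- integer(0)
  j_col <- integer(0)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      open <- c(open, k)
    } else if (chars[k] == ")") {
      if (!length(open)) {
        stop(sprintf("unbalanced dot-bracket: unmatched ')' at position %d", k),
             call. = FALSE)
      }
      i_col <- c(i_col, open[length(open)])
      j_col <- c(j_col, k)
      open <- open[-length(open)]
    }
  }
  if (length(open)) {
    stop(sprintf("unbalanced dot-bracket: unmatched '(' at position %d",
                 open[1]), call. = FALSE)
  }
  ord <- order(i_col)
  pairs <- cbind(i = i_col[ord], j = j_col[ord])
  list(dotbracket = db, pairs = pairs)
}

#' Render base pairs back to dot-bracket
#'
#' Inverse of [parse_dotbracket()] for nested pair sets.
#'
#' @param pairs Integer matrix with columns `i`, `j` (1-based).
#' @param n Sequence length.
#' @return Dot-bracket string of length `n`.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  out <- rep(".", n)
  if (NROW(pairs)) {
    out[pairs[, 1]] <- "("
    out[pairs[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

#' Read FASTA or dot-bracket-extended FASTA
#'
#' Each record is a `>`-header, one or more sequence lines (concatenated;
#' blank lines ignored), and optionally one structure line consisting of
#' `.`, `(`, `)` characters, optionally followed by a whitespace-separated
#' parenthesised free energy (as printed by RNAfold), which is stripped.
#'
#' @param path Path to the file, or a character vector of lines via `text`.
#' @param text Optional character scalar/vector of raw content, used instead
#'   of `path`.
#' @return A list of [rna_record()] objects, in file order.
#' @examples
#' recs <- read_rna_fasta(text = ">x\nGGGAAACCC\n(((...)))  (-1.20)\n")
#' recs[[1]]$structure
#' @export
read_rna_fasta <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(is.character(path), length(path) == 1L)
    lines <- readLines(path, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA input", call. = FALSE)
  if (!startsWith(lines[1], ">")) {
    stop("malformed FASTA: first non-blank line must start with '>' (line 1: '",
         lines[1], "')", call. = FALSE)
  }
  records <- list()
  id <- NULL
  seq_parts <- character(0)
  struct <- NULL
  flush <- function() {
    if (is.null(id)) return()
    if (!length(seq_parts)) {
      stop(sprintf("record '%s' has no sequence line", id), call. = FALSE)
    }
    records[[length(records) + 1L]] <<-
      rna_record(id, paste(seq_parts, collapse = ""), struct)
  }
  for (line in lines) {
    if (startsWith(line, ">")) {
      flush()
      id <- trimws(substring(line, 2))
      if (!nzchar(id)) stop("malformed FASTA header: '>' with empty id",
                            call. = FALSE)
      seq_parts <- character(0)
      struct <- NULL
    } else if (is_structure_line(line)) {
      if (!is.null(struct)) {
        stop(sprintf("record '%s' has more than one structure line", id),
             call. = FALSE)
      }
      struct <- strip_energy_annotation(trimws(line))
    } else {
      if (!is.null(struct)) {
        stop(sprintf(
          "record '%s': sequence line after structure line", id), call. = FALSE)
      }
      seq_parts <- c(seq_parts, trimws(line))
    }
  }
  flush()
  records
}

#' Write records in the dot-bracket-extended FASTA dialect
#'
#' @param records List of [rna_record()] objects.
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_rna_fasta <- function(records, path = NULL) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0(">", r$id), r$sequence,
      if (!is.null(r$structure)) r$structure)
  }), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
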