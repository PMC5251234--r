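#' Folding backends
#'
#' A folding backend turns an RNA sequence into a dot-bracket structure of
#' equal length. Two backends are provided:
#'
#' * `"nussinov"` — the built-in, dependency-free fallback: maximum base
#'   pairing over \{AU, UA, GC, CG, GU, UG\} with a minimum hairpin loop,
#'   computed by the classic O(N^3) dynamic program with a fixed traceback
#'   tie-break, so it is fully deterministic. This is a combinatorial
#'   maximum-pairing model, not a thermodynamic minimum-free-energy model.
#' * `"external"` — the ViennaRNA `RNAfold` minimum-free-energy predictor,
#'   called as a subprocess when the binary is on the PATH.
#'
#' @param name `"nussinov"`, `"external"`, or `"auto"` (external if the
#'   `RNAfold` binary is found, else nussinov, with a notice).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (nussinov backend only).
#' @return An object of class `fold_backend`: a list with `name` and
#'   `fold(seq)`.
#' @examples
#' b <- fold_backend("nussinov")
#' b$fold("GGGAAACCC")
#' @export
fold_backend <- function(name = c("auto", "nussinov", "external"),
                         min_loop = 3L) {
  name <- match.arg(name)
  if (name == "auto") {
    if (nzchar(Sys.which("RNAfold"))) {
      name <- "external"
    } else {
      message("RNAfold not found on PATH; using the built-in nussinov backend")
      name <- "nussinov"
    }
  }
  fold <- switch(name,
    nussinov = function(seq) fold_nussinov(seq, min_loop = min_loop),
    external = fold_external
  )
  structure(list(name = name, fold = fold), class = "fold_backend")
}

#' Maximum base-pairing fold (Nussinov dynamic program)
#'
#' Maximises the number of nested base pairs among \{AU, UA, GC, CG, GU, UG\}
#' subject to a minimum hairpin loop of `min_loop` unpaired bases. The
#' traceback tie-break is fixed — prefer leaving position `i` unpaired, else
#' pair `i` with the smallest admissible partner — so the returned structure
#' is deterministic.
#'
#' @param seq RNA sequence string over `A,C,G,U` (`T` accepted).
#' @param min_loop Minimum hairpin loop size (default 3, the steric minimum).
#' @return Dot-bracket string of the same length as `seq`.
#' @examples
#' fold_nussinov("GGGAAACCC")   # "(((...)))"
#' @export
fold_nussinov <- function(seq, min_loop = 3L) {
  s <- strsplit(normalize_sequence(seq), "")[[1]]
  n <- length(s)
  if (n == 0L) return("")
  can_pair <- outer(s, s, FUN = function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  })
  m <- matrix(0L, n, n)
  if (n >= min_loop + 2L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in 1L:(n - span)) {
        j <- i + span
        best <- m[i + 1L, j] # i unpaired
        ks <- (i + min_loop + 1L):j
        ks <- ks[can_pair[i, ks]]
        if (length(ks)) {
          inner <- ifelse(ks - 1L >= i + 1L, m[cbind(i + 1L, ks - 1L)], 0L)
          right <- ifelse(ks + 1L <= j, m[cbind(pmin(ks + 1L, n), j)], 0L)
          right[ks + 1L > j] <- 0L
          best <- max(best, max(inner + right + 1L))
        }
        m[i, j] <- best
      }
    }
  }
  # iterative traceback over an explicit interval stack
  db <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j && m[i, j] > 0L) {
      if (m[i, j] == m[i + 1L, j]) { # prefer i unpaired
        i <- i + 1L
        next
      }
      ks <- (i + min_loop + 1L):j
      ks <- ks[can_pair[i, ks]]
      paired <- FALSE
      for (k in ks) { # smallest admissible partner first
        inner <- if (k - 1L >= i + 1L) m[i + 1L, k - 1L] else 0L
        right <- if (k + 1L <= j) m[k + 1L, j] else 0L
        if (m[i, j] == inner + right + 1L) {
          db[i] <- "("; db[k] <- ")"
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) stop("internal error: traceback failed") # nocov
    }
  }
  paste(db, collapse = "")
}

#' Fold with the external ViennaRNA RNAfold predictor
#'
#' Runs `RNAfold --noPS` as a subprocess and returns its minimum free energy
#' structure, with the energy annotation discarded. Tool defaults are used
#' for temperature and dangling-end options.
#'
#' @param seq RNA sequence string.
#' @return Dot-bracket string of the same length as `seq`.
#' @export
fold_external <- function(seq) {
  seq <- normalize_sequence(seq)
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop("folding backend unavailable: RNAfold not found on PATH; ",
         "select the 'nussinov' backend instead", call. = FALSE)
  }
  out <- system2(exe, args = "--noPS", input = seq, stdout = TRUE)
  struct_line <- out[grepl("^[.()]", out)][1]
  if (is.na(struct_line)) {
    stop("RNAfold produced no structure line for sequence '", seq, "'",
         call. = FALSE)
  }
  db <- strsplit(struct_line, " ", fixed = TRUE)[[1]][1]
  if (nchar(db) != nchar(seq)) {
    stop("RNAfold structure length mismatch", call. = FALSE) # nocov
  }
  db
}

#' Ensure a record carries a structure
#'
#' Returns the record unchanged if it already has a structure, otherwise
#' folds the sequence with the given backend.
#'
#' @param rec An [rna_record()].
#' @param backend A [fold_backend()].
#' @return An [rna_record()] with a structure.
#' @export
ensure_structure <- function(rec, backend = fold_backend("nussinov")) {
  stopifnot(inherits(rec, "rna_record"))
  if (!is.null(rec$structure)) return(rec)
  rna_record(rec$id, rec$sequence, backend$fold(rec$sequence))
}
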