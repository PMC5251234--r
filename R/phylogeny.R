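#' All-pairs structural distance matrix
#'
#' Folds missing structures, encodes every record as a TV-curve and fills a
#' symmetric matrix with `D[i, j] = 1 - multiscale_similarity(curve_i,
#' curve_j)`. Each of the `n(n-1)/2` pairs is computed once and mirrored;
#' the diagonal is zero. Wavelet decompositions are cached per record and
#' common resampling length, so sets of equal-length records decompose each
#' record only once.
#'
#' @param records List of [rna_record()] objects, at least 3.
#' @param cfg A [tvc_config()].
#' @param backend A [fold_backend()].
#' @param min_len Minimal accepted sequence length.
#' @return Object of class `tvc_distmat`: list with `labels` and `D`
#'   (symmetric numeric matrix with dimnames).
#' @export
pairwise_distance_matrix <- function(records, cfg = tvc_config(),
                                     backend = fold_backend("nussinov"),
                                     min_len = 10L) {
  stopifnot(length(records) >= 3L)
  records <- lapply(records, validate_record, min_len = min_len)
  labels <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(labels)) {
    stop("record ids must be unique for distance-matrix construction",
         call. = FALSE)
  }
  curves <- lapply(records, function(r) tv_curve(ensure_structure(r, backend)))
  signals <- lapply(curves, extract_signal, kind = cfg$signal)
  cache <- new.env(parent = emptyenv())
  decomp <- function(i, len) {
    key <- paste0(i, ":", len)
    if (is.null(cache[[key]])) {
      cache[[key]] <- wavelet_decompose(resample_signal(signals[[i]], len), cfg)
    }
    cache[[key]]
  }
  n <- length(records)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      len <- next_pow2(max(length(signals[[i]]), length(signals[[j]])))
      da <- decomp(i, len)
      db <- decomp(j, len)
      levels <- min(da$levels, db$levels)
      w <- cfg$weights
      if (levels != cfg$levels) {
        w <- w[seq_len(levels + 1L)]
        w <- w / sum(w)
      }
      score <- w[1L] * level_correlation(da$approx, db$approx)
      for (l in seq_len(levels)) {
        score <- score + w[l + 1L] *
          level_correlation(da$details[[l]], db$details[[l]])
      }
      D[i, j] <- D[j, i] <- similarity_to_distance(score)
    }
  }
  structure(list(labels = labels, D = D), class = "tvc_distmat")
}

#' @export
print.tvc_distmat <- function(x, digits = 6, ...) {
  cat(sprintf("Structural distance matrix over %d records\n", length(x$labels)))
  print(round(x$D, digits))
  invisible(x)
}

#' Write a distance matrix as TSV with label header row and column
#'
#' @param dm A `tvc_distmat` (or plain symmetric matrix with dimnames).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distmat_tsv <- function(dm, path) {
  D <- if (inherits(dm, "tvc_distmat")) dm$D else dm
  df <- data.frame(id = rownames(D), round(D, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_dist_matrix <- function(D) {
  if (inherits(D, "tvc_distmat")) D <- D$D
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (any(abs(D - t(D)) > 1e-12)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(diag(D) != 0)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (any(D < 0)) stop("distances must be nonnegative", call. = FALSE)
  D
}

#' UPGMA clustering of a distance matrix
#'
#' Classic unweighted pair-group method with arithmetic mean: repeatedly
#' merge the pair of clusters at minimal distance and replace their rows by
#' the size-weighted mean of the two (equivalently, the plain mean of all
#' cross-cluster leaf distances). Equal minima are broken deterministically
#' by the lexicographically smallest pair of cluster labels, a cluster being
#' labelled by its smallest descendant leaf label.
#'
#' The result is `hclust`-compatible — heights are cluster-merge distances,
#' so [stats::cophenetic()] and [stats::cutree()] apply directly — and
#' additionally carries the ultrametric node heights (half the merge
#' distance) used for Newick branch lengths.
#'
#' @param D A `tvc_distmat`, `dist`, or symmetric matrix with zero diagonal.
#' @return Object of class `c("tvc_upgma", "hclust")`.
#' @examples
#' D <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' to_newick(upgma(D))   # "(A:0.2,B:0.2);"
#' @export
upgma <- function(D) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  stopifnot(n >= 2L)
  labels <- rownames(D)
  # active cluster bookkeeping
  id <- -seq_len(n)               # hclust convention: negative = leaf
  size <- rep(1L, n)
  rep_label <- labels             # smallest descendant label per cluster
  active <- seq_len(n)
  W <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    # minimal off-diagonal distance among active clusters
    best <- NULL
    for (ai in seq_along(active)[-length(active)]) {
      for (aj in (ai + 1L):length(active)) {
        i <- active[ai]; j <- active[aj]
        d <- W[i, j]
        lab <- sort(c(rep_label[i], rep_label[j]))
        if (is.null(best) || d < best$d - 0 ||
            (d == best$d && (lab[1] < best$lab[1] ||
                             (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = d, lab = lab)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort_merge_pair(id[i], id[j])
    height[step] <- best$d
    # size-weighted update into slot i; retire slot j
    for (k in setdiff(active, c(i, j))) {
      W[i, k] <- W[k, i] <- (size[i] * W[i, k] + size[j] * W[j, k]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    rep_label[i] <- min(rep_label[i], rep_label[j])
    id[i] <- step
    active <- setdiff(active, j)
  }
  out <- structure(
    list(merge = merge, height = height, order = integer(0),
         labels = labels, method = "upgma (average)",
         call = match.call(), dist.method = "tvcurve",
         node_height = height / 2),
    class = c("tvc_upgma", "hclust")
  )
  out$order <- order_leaves(out)
  out
}

sort_merge_pair <- function(a, b) {
  # hclust convention: singletons (negative) before clusters, then ascending
  if (a < 0 && b < 0) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}

order_leaves <- function(tree) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(tree$merge[node, 1]), walk(tree$merge[node, 2]))
  }
  walk(nrow(tree$merge))
}

#' Render a UPGMA tree as a Newick string
#'
#' Branch lengths are parent node height minus child node height on the
#' ultrametric scale (leaf-to-merge-point heights, i.e. half the cluster
#' distances). Children are ordered lexicographically by their smallest
#' descendant label; labels needing it are single-quoted per Newick
#' convention. The string ends with a semicolon.
#'
#' @param tree A `tvc_upgma` from [upgma()].
#' @param digits Number of significant branch-length digits.
#' @return Newick string.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "tvc_upgma"))
  quote_label <- function(lab) {
    if (grepl("[^A-Za-z0-9_.|-]", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else lab
  }
  fmt <- function(x) format(x, digits = digits, scientific = FALSE,
                            trim = TRUE)
  # returns list(text, min_label) for node: negative = leaf, positive = merge
  render <- function(node, parent_h) {
    if (node < 0) {
      lab <- tree$labels[-node]
      return(list(text = paste0(quote_label(lab), ":", fmt(parent_h)),
                  min_label = lab))
    }
    h <- tree$node_height[node]
    kids <- lapply(tree$merge[node, ], render, parent_h = h)
    kids <- kids[order(vapply(kids, `[[`, "", "min_label"))]
    list(
      text = paste0("(", paste(vapply(kids, `[[`, "", "text"),
                               collapse = ","), "):", fmt(parent_h - h)),
      min_label = kids[[1]]$min_label
    )
  }
  root <- nrow(tree$merge)
  h <- tree$node_height[root]
  kids <- lapply(tree$merge[root, ], render, parent_h = h)
  kids <- kids[order(vapply(kids, `[[`, "", "min_label"))]
  paste0("(", paste(vapply(kids, `[[`, "", "text"), collapse = ","), ");")
}

#' Write a Newick file
#'
#' @param tree A `tvc_upgma`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}
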