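#' Pairwise p-distance on an aligned protein set
#'
#' `d(i, j)` is the fraction of mismatching positions among columns where
#' neither sequence has a gap (`-`), the simplest defensible distance for
#' subgroup classification of closely related MYB proteins. A pair sharing no
#' ungapped column has undefined distance and raises an error.
#'
#' @param aln Named character vector of equal-length aligned amino-acid
#'   strings (gaps `-`), or a `Biostrings::AAStringSet`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aln) {
  if (inherits(aln, "AAStringSet")) aln <- setNames(as.character(aln), names(aln))
  if (is.null(names(aln)) || anyDuplicated(names(aln))) {
    abort("alignment sequences must have unique names")
  }
  L <- unique(nchar(aln))
  if (length(L) != 1) abort("aligned sequences must all have the same length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        abort(sprintf("undefined distance: '%s' and '%s' share no ungapped column",
                      names(aln)[i], names(aln)[j]))
      }
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: repeatedly join the pair minimising
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j`, with branch lengths from the
#' standard three-point formulas and distances to the new node
#' `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. Ties in Q are broken
#' deterministically on the lexicographically smallest pair of member ids, so
#' the output is invariant under permutation of the input taxa. Negative
#' branch lengths are clamped to zero and flagged via the
#' `"negative_branch_clamped"` attribute. On an additive (tree-metric) input
#' the generating topology is recovered exactly.
#'
#' @param dm Symmetric distance matrix with unique row/column names (>= 3
#'   taxa), e.g. from [p_distance()].
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (!all(is.finite(dm))) abort("non-finite distances")
  n <- nrow(dm)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  ids <- rownames(dm)
  fmt <- function(x) sprintf("%.12g", max(0, x))
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(0, x)
  }
  # active clusters as Newick fragments; rep_id = lexicographically smallest
  # member id, used for the deterministic tie-break
  node <- ids
  rep_id <- ids
  D <- dm

  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ix) {
      pair <- sort(c(rep_id[ix[1]], rep_id[ix[2]]))
      paste(pair, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- D[i, j]
    vi <- clamp(dij / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(dij - (dij / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    new_node <- paste0("(", node[i], ":", fmt(vi), ",", node[j], ":", fmt(vj), ")")
    new_rep <- min(rep_id[i], rep_id[j])
    dk <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], new_node)
    rep_id <- c(rep_id[keep], new_rep)
    D <- D2
  }
  v <- c(
    (D[1, 2] + D[1, 3] - D[2, 3]) / 2,
    (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
    (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  )
  newick <- paste0("(", node[1], ":", fmt(clamp(v[1])), ",",
                   node[2], ":", fmt(clamp(v[2])), ",",
                   node[3], ":", fmt(clamp(v[3])), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_branch_clamped") <- clamped
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree from [p_distance()], then resamples alignment
#' columns with replacement `replicates` times, rebuilds the tree per
#' replicate, and annotates each internal edge of the full-data tree with the
#' percentage of replicates containing that bipartition (stored as
#' `node.label`). Seeded and reproducible: the same seed yields identical
#' supports. With `replicates = 0` the tree carries no support annotations.
#'
#' @param aln Named character vector of aligned amino-acid strings.
#' @param replicates Number of bootstrap replicates, default 1000.
#' @param seed Integer RNG seed.
#' @return An `ape::phylo` tree; internal-node labels are support percentages.
#' @export
bootstrap_support <- function(aln, replicates = 1000, seed = 1) {
  if (inherits(aln, "AAStringSet")) aln <- setNames(as.character(aln), names(aln))
  stopifnot(replicates >= 0)
  main <- neighbor_joining(p_distance(aln))
  if (replicates == 0) return(main)
  cols <- do.call(rbind, strsplit(toupper(aln), ""))
  L <- ncol(cols)
  boots <- withr::with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      idx <- sample.int(L, L, replace = TRUE)
      resampled <- setNames(apply(cols[, idx, drop = FALSE], 1, paste, collapse = ""),
                            names(aln))
      tryCatch(neighbor_joining(p_distance(resampled)), error = function(e) NULL)
    })
  })
  boots <- boots[!vapply(boots, is.null, TRUE)]
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / length(boots))
  main$node.label <- as.character(support)
  # the root "bipartition" of an unrooted tree is not an internal edge
  main$node.label[1] <- ""
  main
}

#' Assign query proteins to reference subgroups on a tree
#'
#' For each query leaf, finds the smallest bipartition side (clade induced by
#' an internal or terminal edge) containing the query and at least one
#' reference; the query is assigned that subgroup iff every reference in the
#' side carries the same label, otherwise `"unassigned"`. This mirrors the
#' practice of classifying candidate MYBs as SG5 / SG47 by their placement
#' among reference R2R3 MYBs.
#'
#' @param tree An `ape::phylo` tree containing query and reference leaves.
#' @param reference_labels Named character vector: reference leaf id ->
#'   subgroup label (e.g. `"SG5"`, `"SG47"`).
#' @param queries Query leaf ids; defaults to all non-reference leaves.
#' @return Tibble `query`, `subgroup`, `clade_size`.
#' @export
assign_subgroup <- function(tree, reference_labels, queries = NULL) {
  tips <- tree$tip.label
  refs <- names(reference_labels)
  if (length(intersect(refs, tips)) == 0) abort("no reference leaves in tree")
  if (is.null(queries)) queries <- setdiff(tips, refs)
  absent <- setdiff(queries, tips)
  if (length(absent) > 0) {
    abort(paste0("query absent from tree: ", paste(absent, collapse = ", ")))
  }
  # every edge-induced bipartition side, as tip-label sets
  parts <- ape::prop.part(tree)
  labels <- attr(parts, "labels")
  sides <- lapply(parts, function(p) labels[p])
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)),
             as.list(tips), lapply(tips, function(t) setdiff(tips, t)))
  sizes <- lengths(sides)

  purrr::map_dfr(queries, function(q) {
    cand <- which(vapply(sides, function(s) q %in% s && any(refs %in% s), TRUE))
    if (length(cand) == 0) {
      return(tibble(query = q, subgroup = "unassigned", clade_size = NA_integer_))
    }
    best <- cand[sizes[cand] == min(sizes[cand])]
    lab <- unique(unlist(lapply(best, function(k) {
      unique(reference_labels[intersect(refs, sides[[k]])])
    })))
    tibble(
      query = q,
      subgroup = if (length(lab) == 1) lab else "unassigned",
      clade_size = min(sizes[cand])
    )
  })
}

#' Read an aligned FASTA file of protein sequences
#'
#' @param path FASTA path.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
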