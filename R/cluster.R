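# Descriptor-space hierarchical clustering: min-max normalization and
# Ward reciprocal-nearest-neighbor agglomeration (exact centroid/size update,
# heights on the ward.D2 scale), with dendrogram export as Newick.

#' Min-max normalize a descriptor matrix
#'
#' Scales every column to the unit interval; a constant column becomes all
#' zeros with a warning.
#'
#' @param x numeric matrix or data.frame (rows = peptides, columns =
#'   descriptors, canonically `E_M`, `E_S`, `L_M`, `L_S_star`).
#' @return numeric matrix with the same dimnames, all values in 0..1.
#' @export
normalize_descriptors <- function(x) {
  m <- as.matrix(x)
  if (nrow(m) < 2) stop("need at least two rows", call. = FALSE)
  if (anyNA(m)) {
    bad <- rownames(m)[apply(is.na(m), 1, any)]
    stop("missing descriptor values for: ",
         paste(if (is.null(bad)) which(apply(is.na(m), 1, any)) else bad,
               collapse = ", "), call. = FALSE)
  }
  rng <- apply(m, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0))
    warning("constant descriptor column(s) mapped to 0: ",
            paste(colnames(m)[span == 0], collapse = ", "), call. = FALSE)
  out <- sweep(m, 2, rng[1, ])
  out <- sweep(out, 2, ifelse(span == 0, 1, span), `/`)
  out
}

# Ward merge cost between clusters (size, centroid): on the scale used by
# hclust's ward.D2 (two singletons merge at their Euclidean distance).
.ward_cost <- function(na, ca, nb, cb) {
  sqrt(2 * na * nb / (na + nb)) * vnorm(ca - cb)
}

#' Ward hierarchical clustering (reciprocal nearest neighbors)
#'
#' Agglomerative Ward clustering computed exactly from cluster sizes and
#' centroids: at each step the reciprocal-nearest-neighbor pair under the
#' Ward merge cost is merged (Ward's criterion is reducible, so this yields
#' the same dendrogram as the classical Lance-Williams recurrence). Heights
#' are on the same scale as `hclust(..., method = "ward.D2")`.
#'
#' @param x numeric matrix of observations (rows) by features (columns);
#'   normally the output of [normalize_descriptors()].
#' @param labels optional leaf labels (default rownames or 1..n).
#' @return object of class `ward_tree` (and `hclust`): `merge`, `height`,
#'   `order`, `labels`.
#' @export
ward_cluster <- function(x, labels = NULL) {
  m <- as.matrix(x)
  n <- nrow(m)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  if (is.null(labels)) labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  size <- rep(1, n)
  cent <- m
  id <- -seq_len(n)            # hclust convention: negatives are leaves
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  # pairwise ward costs
  cost <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cost[i, j] <- cost[j, i] <- .ward_cost(1, m[i, ], 1, m[j, ])
    }
  }
  for (step in seq_len(n - 1)) {
    act <- which(active)
    sub <- cost[act, act, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- act[min(k[1], k[2])]; j <- act[max(k[1], k[2])]
    height[step] <- cost[i, j]
    merge[step, ] <- sort(c(id[i], id[j]))
    # merged cluster replaces i
    ni <- size[i]; nj <- size[j]
    cent[i, ] <- (ni * cent[i, ] + nj * cent[j, ]) / (ni + nj)
    size[i] <- ni + nj
    id[i] <- step
    active[j] <- FALSE
    cost[j, ] <- cost[, j] <- Inf
    for (o in which(active)) {
      if (o == i) next
      cost[i, o] <- cost[o, i] <- .ward_cost(size[i], cent[i, ],
                                             size[o], cent[o, ])
    }
  }
  tree <- structure(list(merge = merge, height = height,
                         order = integer(n), labels = labels,
                         method = "ward.rnn",
                         call = match.call(),
                         dist.method = "euclidean"),
                    class = c("ward_tree", "hclust"))
  tree$order <- stats::order.dendrogram(stats::as.dendrogram(
    structure(tree, class = "hclust")))
  tree
}

#' Cut a cluster tree into k groups
#'
#' @param tree a `ward_tree` (or any `hclust`).
#' @param k number of groups (2 <= k <= leaves).
#' @return integer group assignment named by leaf labels.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$height) + 1
  if (k > n) stop("k exceeds the number of leaves", call. = FALSE)
  stats::cutree(structure(tree, class = "hclust"), k = k)
}

#' Export a cluster tree as Newick
#'
#' Merge heights become branch lengths, so the text round-trips through any
#' standard tree reader.
#'
#' @param tree a `ward_tree`.
#' @param path output file; when NULL the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(structure(tree, class = "hclust"))
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Compose dendrogram leaf labels
#'
#' Standard label format `G<group>-<class>-<label>`, e.g. `"G1-A2-M33"`:
#' cluster group, relative-activity class and the peptide's subfamily label.
#'
#' @param group integer group ids (e.g. from [cut_clusters()]).
#' @param activity_class classes from [classify_activity()].
#' @param label peptide labels (subfamily letter + number).
#' @return character vector.
#' @export
leaf_labels <- function(group, activity_class, label) {
  sprintf("G%d-%s-%s", group, activity_class, label)
}

#' Rand index between two partitions
#'
#' Fraction of object pairs on which two partitions agree (both together or
#' both apart).
#'
#' @param a,b integer/factor vectors of equal length.
#' @return Rand index in 0..1.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  sa <- outer(a, a, `==`)
  sb <- outer(b, b, `==`)
  up <- upper.tri(sa)
  mean(sa[up] == sb[up])
}
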