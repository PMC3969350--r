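# Template selection from a bootstrap-annotated tree: given a target leaf and
# the set of leaves with known (solved) structures, pick one or two modeling
# templates according to the topology around the target and the bootstrap
# support of its parent node.

#' Read a support-annotated tree
#'
#' Reads a Newick tree whose internal-node labels are bootstrap support
#' percentages (0..100).
#'
#' @param path Newick file path (or a Newick string via `text`).
#' @param text optional Newick string.
#' @return an `ape::phylo` with numeric `node.support` attached.
#' @export
read_support_tree <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  if (!is.null(sup) && any(!is.na(sup) & (sup < 0 | sup > 100)))
    stop("bootstrap support values must lie in 0..100", call. = FALSE)
  attr(tr, "node.support") <- sup
  tr
}

# topological (edge-count) distances between all leaves
.leaf_path_lengths <- function(tree) {
  t1 <- tree
  t1$edge.length <- rep(1, nrow(t1$edge))
  d <- ape::dist.nodes(t1)
  ntip <- length(tree$tip.label)
  d[seq_len(ntip), seq_len(ntip), drop = FALSE]
}

#' Select modeling templates for a target sequence
#'
#' Rules, applied to the clade that is sister to the target leaf:
#' \itemize{
#' \item the sister is a single leaf of known structure `b`: take `{b}` when
#'   the bootstrap support of their common ancestor exceeds 50%, otherwise
#'   `{b, c}` where `c` is the nearest other known leaf by topological path
#'   length (ties broken alphabetically);
#' \item the sister clade consists of exactly two known leaves `b, c`: take
#'   `{b, c}` regardless of the support value;
#' \item the sister clade contains two or more known leaves (other shapes):
#'   take two of them uniformly at random (seeded);
#' \item otherwise fall back to the nearest known leaf.
#' }
#'
#' @param tree a tree from [read_support_tree()].
#' @param target target leaf label.
#' @param known character vector of leaf labels with known structures.
#' @param seed integer seed for the random rule.
#' @return character vector of 1 or 2 template labels, with attribute
#'   `rule` (one of `"A"`, `"B"`, `"C"`, `"fallback"`).
#' @export
select_templates <- function(tree, target, known, seed = 1) {
  tips <- tree$tip.label
  if (!target %in% tips) stop("target leaf not in tree", call. = FALSE)
  known <- setdiff(intersect(known, tips), target)
  if (length(known) == 0) stop("no leaves of known structure", call. = FALSE)
  ntip <- length(tips)
  tgt <- match(target, tips)
  edge <- tree$edge
  parent <- edge[edge[, 2] == tgt, 1]
  sup <- attr(tree, "node.support")
  support_at <- function(node) {
    s <- if (is.null(sup)) NA_real_ else sup[node - ntip]
    if (length(s) == 0 || is.na(s)) 0 else s
  }
  pl <- .leaf_path_lengths(tree)
  nearest_known <- function(exclude = character(0)) {
    cand <- setdiff(known, exclude)
    if (!length(cand)) return(character(0))
    d <- pl[tgt, match(cand, tips)]
    cand <- cand[order(d, cand, method = "radix")]
    cand[1]
  }
  # sister nodes: other children of the parent
  sisters <- edge[edge[, 1] == parent & edge[, 2] != tgt, 2]
  clade_tips <- function(node) {
    if (node <= ntip) return(tips[node])
    ape::extract.clade(tree, node)$tip.label
  }
  sister_leaves <- unlist(lapply(sisters, clade_tips))
  sister_known <- intersect(sister_leaves, known)

  if (length(sisters) == 1 && sisters <= ntip) {
    b <- tips[sisters]
    if (b %in% known) {                       # case A
      if (support_at(parent) > 50) {
        out <- b
      } else {
        out <- c(b, nearest_known(exclude = b))
      }
      attr(out, "rule") <- "A"
      return(out)
    }
  } else if (length(sister_leaves) == 2 && length(sister_known) == 2) {
    out <- sort(sister_known)                 # case B
    attr(out, "rule") <- "B"
    return(out)
  } else if (length(sister_known) >= 2) {     # case C
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
    out <- sample(sort(sister_known), 2)
    attr(out, "rule") <- "C"
    return(out)
  }
  out <- nearest_known()                      # fallback
  attr(out, "rule") <- "fallback"
  out
}
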