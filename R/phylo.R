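#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` the transition and
#' `Q` the transversion fraction over sites where both sequences carry an
#' unambiguous base (gaps and `N` excluded pairwise). Mitochondrial data
#' are strongly transition-biased, which is exactly what the two-parameter
#' correction absorbs.
#'
#' @param a,b Aligned sequences (equal-length character scalars, or
#'   character vectors of single bases).
#' @return The distance (substitutions/site); `NA` on saturation (log
#'   argument <= 0).
#' @export
k2p_distance <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(a, "")[[1]] else a
  bv <- if (length(b) == 1L) strsplit(b, "")[[1]] else b
  stopifnot(length(av) == length(bv))
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  if (n == 0L) return(NA_real_)
  diff <- av != bv
  ts <- sum(diff & TRANSITION[av] == bv)
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

as_aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  stopifnot(is.character(alignment), !is.null(names(alignment)),
            length(unique(nchar(alignment))) == 1L)
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Kimura two-parameter distance matrix of an alignment
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, or a character matrix (taxa x sites).
#' @return Symmetric distance matrix with taxa dimnames.
#' @export
k2p_matrix <- function(alignment) {
  m <- as_aln_matrix(alignment)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- k2p_distance(m[i, ], m[j, ])
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion,
#' `Q_ij = (n-2) d_ij - r_i - r_j`; ties are broken deterministically by
#' the lexicographically smallest pair of taxon labels. Negative branch
#' lengths (which NJ can produce on non-additive matrices) are clamped to
#' zero on output and counted in the `negative_branches` attribute.
#'
#' @param m Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(m) {
  m <- as.matrix(m)
  labels <- rownames(m)
  n <- nrow(m)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(is.na(m))) stop("distance matrix contains NA", call. = FALSE)
  neg <- 0L
  fmt <- function(x) {
    if (x < 0) neg <<- neg + 1L
    sprintf("%.10f", max(x, 0))
  }
  sub <- labels # newick fragment per active cluster
  D <- m
  active <- seq_len(n)
  while (length(active) > 3L) {
    k <- length(active)
    r <- rowSums(D)
    q <- (k - 2) * D - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    # deterministic tie-break: smallest sorted label pair
    keys <- apply(best, 1L, function(ij)
      paste(sort(c(sub[ij[1]], sub[ij[2]])), collapse = "\r"))
    pick <- best[order(keys)[1L], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
    active <- seq_len(k - 1L)
  }
  # three-point resolution of the final trifurcation
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(l1), sub[2], fmt(l2),
                 sub[3], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_branches") <- neg
  tree
}

# canonical bipartition keys of the internal edges of an unrooted tree:
# each split is represented by the tip-label side not containing the
# alphabetically first label, sorted and collapsed
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  post <- stats::reorder(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  anchor <- sort(tree$tip.label)[1]
  keys <- character(0)
  nodes <- integer(0)
  for (v in (n + 1L):(n + tree$Nnode)) {
    if (v == root) next
    side <- desc[[v]]
    if (length(side) < 2L || length(side) > n - 2L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, v)
  }
  list(keys = keys, nodes = nodes)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' K2P-distance NJ tree per replicate, and attaches the frequency of each
#' internal split of the point-estimate tree as its node label
#' (percentage of replicates).
#'
#' @param alignment Named character vector or character matrix
#'   (taxa x sites) of aligned sequences.
#' @param n_reps Number of bootstrap replicates (0 = point tree only).
#' @param seed Integer seed.
#' @return The point-estimate `ape::phylo` tree; with `n_reps > 0`,
#'   `node.label` holds split supports (root label empty) and the
#'   `"supports"` attribute a tibble of split keys and percentages.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  m <- as_aln_matrix(alignment)
  tree <- nj_tree(k2p_matrix(m))
  if (n_reps <= 0L) return(tree)
  set.seed(as.integer(seed))
  sp <- tree_splits(tree)
  hit <- stats::setNames(numeric(length(sp$keys)), sp$keys)
  ns <- ncol(m)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ns, ns, replace = TRUE)
    d <- k2p_matrix(m[, cols, drop = FALSE])
    if (any(is.na(d))) next
    rk <- tree_splits(nj_tree(d))$keys
    seen <- sp$keys %in% rk
    hit[seen] <- hit[seen] + 1
  }
  support <- 100 * hit / n_reps
  n <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  lab[sp$nodes - n] <- sprintf("%g", round(support, 1))
  tree$node.label <- lab
  attr(tree, "supports") <- tibble::tibble(split = sp$keys,
                                           support = unname(support))
  tree
}

#' Bootstrap support for the split isolating a set of tips
#'
#' @param tree A tree from [bootstrap_support()].
#' @param tips Tip labels on one side of the split of interest.
#' @return The support percentage, or `NA` if the tree does not contain
#'   that split.
#' @export
clade_support <- function(tree, tips) {
  sup <- attr(tree, "supports")
  if (is.null(sup)) return(NA_real_)
  anchor <- sort(tree$tip.label)[1]
  side <- tips
  if (anchor %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "|")
  i <- match(key, sup$split)
  if (is.na(i)) NA_real_ else sup$support[i]
}

#' Is a set of tips monophyletic in an unrooted tree?
#'
#' True when some internal edge separates exactly `tips` from the rest.
#'
#' @inheritParams clade_support
#' @return Logical.
#' @export
tips_form_clade <- function(tree, tips) {
  anchor <- sort(tree$tip.label)[1]
  side <- tips
  if (anchor %in% side) side <- setdiff(tree$tip.label, side)
  key <- paste(sort(side), collapse = "|")
  key %in% tree_splits(tree)$keys
}
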