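# Tree topology from pairwise MEDs (neighbor joining), rooting at the
# diploid, and minimum-event ancestral genome reconstruction.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \code{ape::nj}) with input validation;
#' negative branch lengths (possible on non-additive matrices) are clamped
#' to zero with a warning.
#'
#' @param D symmetric non-negative matrix with zero diagonal and sample
#'   ids as dimnames; at least 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Root a tree at the diploid leaf
#'
#' Places the root on the diploid's pendant branch so the diploid remains
#' a leaf child of the root.  Idempotent.
#'
#' @param tree a `phylo` containing a leaf named `diploid` (or
#'   `outgroup`).
#' @param outgroup leaf to root at.
#' @return a rooted `phylo`.
#' @export
root_at_diploid <- function(tree, outgroup = "diploid") {
  if (!outgroup %in% tree$tip.label)
    stop("tree has no '", outgroup, "' leaf to root at")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# children/parent helpers on the ape edge matrix
node_children <- function(tree, v) tree$edge[tree$edge[, 1] == v, 2]
node_parent <- function(tree, v) {
  p <- tree$edge[tree$edge[, 2] == v, 1]
  if (length(p) == 0) NA_integer_ else p
}

#' Minimum-event ancestral genome reconstruction
#'
#' Assigns copy-number profiles to the internal nodes of a rooted tree so
#' that the total number of events along the tree (the sum over branches
#' of the asymmetric MED directed away from the diploid root) is small.
#' The root profile is fixed to the diploid.  Internal nodes are
#' initialized bottom-up with the symmetric-MED pair ancestors of their
#' children, then refined by a monotone local search: each node is
#' re-optimized against its parent and children over a candidate set
#' (current profile, pair ancestors with each pair of neighbors, and the
#' neighbor profiles themselves), accepting only strict improvements, so
#' the objective is non-increasing and the search terminates at a local
#' minimum.  With `coordinate_refine = TRUE` an additional coordinate-wise
#' pass over disagreeing segments is run (slower, occasionally tighter).
#'
#' @param tree rooted `phylo` with leaf set equal to the cohort sample ids
#'   (incl. `diploid`).
#' @param cohort the `cn_cohort` carrying the leaf profiles.
#' @param model a `cn_event_model`.
#' @param max_sweeps maximum refinement sweeps.
#' @param coordinate_refine also run coordinate-wise improvement.
#' @return an object of class `cn_phylo`: list with `tree` (branch
#'   lengths = per-branch MEDs), `profiles` (list over node numbers),
#'   `cohort`, `model`.
#' @export
reconstruct_ancestors <- function(tree, cohort, model, max_sweeps = 5L,
                                  coordinate_refine = FALSE) {
  layout <- cohort$layout
  ids <- names(cohort$profiles)
  if (!setequal(tree$tip.label, ids))
    stop("tree leaf set does not match cohort sample ids")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  profiles <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) profiles[[i]] <- cohort$profiles[[tree$tip.label[i]]]
  dip <- diploid_profile(layout, cohort$cap)

  enc <- vector("list", ntip + nnode)
  set_prof <- function(v, p) {
    profiles[[v]] <<- p
    enc[[v]] <<- encode_profile(p, layout)
  }
  for (i in seq_len(ntip)) enc[[i]] <- encode_profile(profiles[[i]], layout)

  pair_anc <- function(p1, p2)
    med_symmetric(p1, p2, model, layout, ancestor = TRUE)$ancestor
  med <- function(a, b)
    chain_shortest_path(model$chain_asym, a, b, model$n_symbols)$weight

  # bottom-up initialization (postorder): fold children pairwise
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  internal_post <- unique(edges[, 1])  # parents in postorder
  for (v in internal_post) {
    if (v == root) next
    ch <- node_children(tree, v)
    p <- profiles[[ch[1]]]
    if (length(ch) > 1)
      for (k in 2:length(ch)) p <- pair_anc(p, profiles[[ch[k]]])
    p$sample_id <- paste0("internal_", v)
    set_prof(v, p)
  }
  set_prof(root, {
    d <- dip; d$sample_id <- "root"; d
  })

  local_cost <- function(v, ev) {
    pa <- node_parent(tree, v)
    cost <- med(enc[[pa]], ev)
    for (c in node_children(tree, v)) cost <- cost + med(ev, enc[[c]])
    cost
  }
  internal_nonroot <- setdiff(ntip + seq_len(nnode), root)

  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (v in internal_nonroot) {
      pa <- node_parent(tree, v)
      ch <- node_children(tree, v)
      cur_cost <- local_cost(v, enc[[v]])
      cands <- list()
      if (length(ch) >= 2)
        cands <- c(cands, list(pair_anc(profiles[[ch[1]]], profiles[[ch[2]]])))
      for (c in ch)
        cands <- c(cands, list(pair_anc(profiles[[pa]], profiles[[c]])),
                   list(profiles[[c]]))
      cands <- c(cands, list(profiles[[pa]]))
      best <- NULL; best_cost <- cur_cost
      for (cand in cands) {
        ec <- encode_profile(cand, layout)
        cc <- local_cost(v, ec)
        if (cc < best_cost) { best <- cand; best_cost <- cc }
      }
      if (!is.null(best)) {
        best$sample_id <- paste0("internal_", v)
        set_prof(v, best)
        changed <- TRUE
      }
      if (coordinate_refine) {
        nb <- c(list(profiles[[pa]]), profiles[ch])
        for (hap in c("hapA", "hapB")) {
          cur <- profiles[[v]]
          vals <- do.call(rbind, lapply(nb, `[[`, hap))
          differ <- which(apply(vals, 2, function(z) length(unique(z)) > 1 ) |
                            vals[1, ] != cur[[hap]])
          for (s in differ) {
            tryv <- unique(vals[, s])
            cur_cost2 <- local_cost(v, enc[[v]])
            for (tv in setdiff(tryv, profiles[[v]][[hap]][s])) {
              cand <- profiles[[v]]
              cand[[hap]][s] <- tv
              ec <- encode_profile(cand, layout)
              cc <- local_cost(v, ec)
              if (cc < cur_cost2) {
                set_prof(v, cand)
                cur_cost2 <- cc
                changed <- TRUE
              }
            }
          }
        }
      }
    }
    if (!changed) break
  }

  # final branch lengths: MED directed away from the root
  elen <- numeric(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    w <- med(enc[[a]], enc[[b]])
    if (!is.finite(w))
      stop("infinite branch MED after reconstruction (inconsistent topology)")
    elen[e] <- w
  }
  tree$edge.length <- elen
  structure(list(tree = tree, profiles = profiles, cohort = cohort,
                 model = model), class = "cn_phylo")
}

#' @export
print.cn_phylo <- function(x, ...) {
  cat(sprintf("<cn_phylo: %d leaves, tree length %d>\n",
              length(x$tree$tip.label), sum(x$tree$edge.length)))
  invisible(x)
}

#' Tree summary statistics
#'
#' Tree length (sum of branch MEDs), trunk length (root to the MRCA of
#' the non-diploid leaves), maximum root-to-leaf length, and the trunk
#' fraction (trunk / max root-to-leaf).
#'
#' @param phy a `cn_phylo` (or a rooted `phylo` with branch lengths and a
#'   `diploid` leaf).
#' @return list with `tree_length`, `trunk_length`, `max_root_to_leaf`,
#'   `trunk_fraction`.
#' @export
tree_stats <- function(phy) {
  tree <- if (inherits(phy, "cn_phylo")) phy$tree else phy
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ingroup <- setdiff(tree$tip.label, "diploid")
  mrca <- if (length(ingroup) > 1)
    ape::getMRCA(tree, ingroup) else which(tree$tip.label == ingroup)
  # path length root -> node
  depth <- ape::node.depth.edgelength(tree)
  tl <- sum(tree$edge.length)
  trunk <- depth[mrca]
  maxrl <- max(depth[seq_len(ntip)][match(ingroup, tree$tip.label)])
  list(tree_length = tl, trunk_length = trunk, max_root_to_leaf = maxrl,
       trunk_fraction = if (maxrl > 0) trunk / maxrl else 1)
}

# canonical split keys of the unrooted topology: for every internal edge,
# the leaf-name set of the smaller side, canonicalized against a
# reference leaf
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- sort(tree$tip.label)
  ref <- labs[1]
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    tips <- tree$tip.label[p]
    if (length(tips) <= 1 || length(tips) >= ntip - 1) next  # trivial split
    if (ref %in% tips) tips <- setdiff(tree$tip.label, tips)
    keys <- c(keys, paste(sort(tips), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted topologies; 0 iff the topologies agree.
#'
#' @param t1,t2 `phylo` trees on the same leaf set.
#' @return integer distance.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have differing leaf sets")
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
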