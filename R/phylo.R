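#' Extract the conserved central domain from an alignment
#'
#' The N- and C-terminal regions of Ggamma subunits vary too much in
#' length to align, so trees are built from the conserved central domain
#' only. The domain window is taken around the `[DE]PL[LI]` anchor:
#' columns `anchor_start_col - upstream` through `anchor_end_col +
#' downstream`, clipped to the alignment. The anchor column is the modal
#' anchor position over the rows; rows in which no anchor is found are
#' dropped with a warning.
#'
#' @param alignment Alignment tibble (columns `id`, `aseq`).
#' @param upstream Columns kept upstream of the anchor start (default 45,
#'   enough to cover all seven Gbeta-contact positions).
#' @param downstream Columns kept downstream of the anchor end (default 2).
#' @return The clipped alignment tibble; the retained column window is in
#'   the `window` attribute.
#' @export
extract_central_domain <- function(alignment, upstream = 45, downstream = 2) {
  alignment <- as_alignment(alignment)
  plain <- degap(alignment$aseq)
  anc <- find_anchor(plain)
  no_anchor <- is.na(anc$anchor_start)
  if (any(no_anchor)) {
    warn(sprintf("dropping %d row(s) without a [DE]PL[LI] anchor: %s",
                 sum(no_anchor), paste(alignment$id[no_anchor], collapse = ", ")))
  }
  alignment <- alignment[!no_anchor, , drop = FALSE]
  anc <- anc[!no_anchor, , drop = FALSE]
  if (nrow(alignment) == 0) stop_gt("no row carries an anchor; empty central domain")
  # map residue positions to alignment columns per row
  start_col <- vapply(seq_len(nrow(alignment)), function(i) {
    map <- which(chars(alignment$aseq[i]) != "-")
    map[anc$anchor_start[i]]
  }, integer(1))
  modal <- as.integer(names(which.max(table(start_col))))
  ncols <- alignment_ncols(alignment)
  from <- max(1L, modal - as.integer(upstream))
  to <- min(ncols, modal + 3L + as.integer(downstream))
  if (to < from) stop_gt("empty central-domain window")
  out <- alignment
  out$aseq <- substr(out$aseq, from, to)
  out <- as_alignment(out)
  attr(out, "window") <- c(from = from, to = to)
  out
}

#' Pairwise distances on an alignment
#'
#' p-distance (mismatches over compared columns) with pairwise deletion:
#' columns where either row has a gap are excluded for that pair; `X`
#' never matches anything, itself included. The Poisson correction
#' `d = -ln(1 - p)` accounts for multiple substitutions; `p` is capped at
#' 0.95 before correction and capped pairs are flagged as saturated.
#'
#' @param alignment Alignment tibble.
#' @param model `"poisson"` (default) or `"p"` for the raw p-distance.
#' @return A symmetric numeric matrix with zero diagonal and the ids as
#'   dimnames; attributes `model` and `saturated` (a two-column matrix of
#'   capped pair ids, possibly empty).
#' @export
seq_distances <- function(alignment, model = c("poisson", "p")) {
  model <- match.arg(model)
  alignment <- as_alignment(alignment)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2) stop_gt("need at least 2 sequences for distances")
  dist_from_matrix(m, model)
}

dist_from_matrix <- function(m, model) {
  n <- nrow(m)
  ids <- rownames(m)
  gap <- m == "-"
  isx <- m == "X"
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0) stop_gt("no comparable columns between '%s' and '%s'", ids[i], ids[j])
      mism <- (m[i, comp] != m[j, comp]) | isx[i, comp] | isx[j, comp]
      p <- sum(mism) / nc
      if (model == "poisson") {
        if (p > 0.95) {
          sat <- rbind(sat, c(ids[i], ids[j]))
          p <- 0.95
        }
        d <- -log(1 - p)
      } else {
        d <- p
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  attr(D, "model") <- model
  attr(D, "saturated") <- if (is.null(sat)) matrix(character(0), ncol = 2) else sat
  D
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix. Ties in the
#' Q-criterion are broken deterministically by the lexicographically
#' smallest pair of cluster representatives (the smallest leaf id in each
#' cluster). A negative branch length arising at a join is floored at zero
#' and the deficit moved to its sister branch, keeping the pairwise path
#' length intact.
#'
#' @param d Symmetric distance matrix with ids as dimnames (or a `dist`),
#'   at least 3 taxa.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) stop_gt("distance matrix needs row/column names")
  if (nrow(d) < 3) stop_gt("neighbor joining needs at least 3 taxa")
  D <- d
  lab <- ids        # newick fragments per active cluster
  rep_id <- ids     # smallest leaf id per cluster, for tie-breaking
  while (length(lab) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    minq <- min(Q)
    hits <- which(Q <= minq + 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    if (nrow(hits) > 1) {
      key <- apply(hits, 1, function(ij) {
        pr <- sort(c(rep_id[ij[1]], rep_id[ij[2]]))
        paste(pr, collapse = "\r")
      })
      hits <- hits[order(key)[1], , drop = FALSE]
    }
    i <- hits[1, 1]; j <- hits[1, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newlab <- sprintf("(%s:%.12g,%s:%.12g)", lab[i], bi, lab[j], bj)
    newrep <- min(rep_id[i], rep_id[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    lab <- c(lab[keep], newlab)
    rep_id <- c(rep_id[keep], newrep)
    dimnames(D2) <- list(rep_id, rep_id)
    D <- D2
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2, (d13 + d23 - d12) / 2)
  b <- pmax(b, 0)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", lab[1], b[1], lab[2], b[2], lab[3], b[3])
  ape::read.tree(text = nwk)
}

# Does `taxa` form one side of a bipartition of the (unrooted) tree?
group_is_split <- function(tree, taxa) {
  labs <- tree$tip.label
  pp <- ape::prop.part(tree)
  for (cl in pp) {
    s <- labs[cl]
    if (length(s) == length(taxa) && setequal(s, taxa)) return(TRUE)
    comp <- setdiff(labs, s)
    if (length(comp) == length(taxa) && setequal(comp, taxa)) return(TRUE)
  }
  FALSE
}

#' Bootstrap bipartition support for labeled groups
#'
#' Resamples alignment columns with replacement, rebuilds a
#' neighbor-joining tree per replicate, and records for each group the
#' fraction of replicates in which its taxa form one side of a bipartition
#' (monophyly on an unrooted tree). One seeded generator drives all
#' replicates in order, so supports are reproducible bit for bit for a
#' given (seed, n_replicates, input). Groups with fewer than 2 or more
#' than n-2 taxa have no defined bipartition; their support is `NA`.
#'
#' @param alignment Alignment tibble, at least 4 taxa.
#' @param groups Data frame with columns `id`, `group` (or a named
#'   character vector id -> group) labeling every taxon.
#' @param n_replicates Number of bootstrap replicates. Default 100.
#' @param seed Integer seed. Default 1.
#' @param model Distance model, see [seq_distances()].
#' @return A `gg_phylo` object: `tree` (the point NJ tree from the
#'   original alignment), `support` (tibble `group`, `support`, `n_taxa`),
#'   `replicate_trees` (a `multiPhylo`), plus `n_replicates`, `seed`,
#'   `model`.
#' @export
bootstrap_support <- function(alignment, groups, n_replicates = 100, seed = 1,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  alignment <- as_alignment(alignment)
  if (nrow(alignment) < 4) stop_gt("bootstrap support needs at least 4 taxa")
  gv <- if (is.data.frame(groups)) stats::setNames(groups$group, groups$id) else groups
  miss <- setdiff(alignment$id, names(gv))
  if (length(miss) > 0) stop_gt("taxa without a group label: %s", paste(miss, collapse = ", "))
  gv <- gv[alignment$id]
  m <- alignment_matrix(alignment)
  ncols <- ncol(m)
  ntax <- nrow(m)
  point_tree <- nj_tree(dist_from_matrix(m, model))
  grp_levels <- unique(gv)
  grp_taxa <- lapply(stats::setNames(grp_levels, grp_levels), function(g) names(gv)[gv == g])
  defined <- vapply(grp_taxa, function(t) length(t) >= 2 && length(t) <= ntax - 2, logical(1))
  hits <- stats::setNames(numeric(length(grp_levels)), grp_levels)
  set.seed(seed)
  rep_trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(ncols, ncols, replace = TRUE)
    tr <- nj_tree(dist_from_matrix(m[, cols, drop = FALSE], model))
    rep_trees[[r]] <- tr
    for (g in grp_levels[defined]) {
      if (group_is_split(tr, grp_taxa[[g]])) hits[g] <- hits[g] + 1
    }
  }
  support <- tibble(
    group = unname(grp_levels),
    support = unname(ifelse(defined, hits / n_replicates, NA_real_)),
    n_taxa = unname(vapply(grp_taxa, length, integer(1)))
  )
  class(rep_trees) <- "multiPhylo"
  structure(list(tree = point_tree, support = support,
                 replicate_trees = rep_trees,
                 n_replicates = n_replicates, seed = seed, model = model),
            class = "gg_phylo")
}

#' Strict majority-rule consensus tree
#'
#' Keeps exactly the bipartitions occurring in strictly more than
#' `threshold` of the input trees (no greedy addition of further
#' compatible splits) and labels each retained internal node with its
#' percentage occurrence.
#'
#' @param trees A list or `multiPhylo` of trees over the same leaf set.
#' @param threshold Retention threshold as a fraction; must be >= 0.5 so
#'   the retained splits are mutually compatible. Default 0.5.
#' @return A `phylo` tree whose node labels are the support percentages.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1) stop_gt("need at least one tree")
  if (threshold < 0.5) stop_gt("threshold below 0.5 can retain incompatible splits")
  labs <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), labs)) stop_gt("trees have different leaf sets")
  }
  ref <- labs[1]
  split_keys <- function(tree) {
    pp <- ape::prop.part(tree)
    tl <- tree$tip.label
    keys <- vapply(pp, function(cl) {
      s <- tl[cl]
      side <- if (ref %in% s) setdiff(labs, s) else s
      paste(sort(side), collapse = "\r")
    }, character(1))
    # drop trivial splits (whole set minus ref, singletons)
    sizes <- vapply(strsplit(keys, "\r", fixed = TRUE), length, integer(1))
    unique(keys[sizes >= 2 & sizes <= length(labs) - 2])
  }
  all_keys <- unlist(lapply(trees, split_keys))
  tab <- table(all_keys)
  freq <- as.numeric(tab) / length(trees)
  keep <- freq > threshold
  splits <- strsplit(names(tab)[keep], "\r", fixed = TRUE)
  supp <- freq[keep]
  # order splits by increasing size; parent = smallest strictly-containing split
  ord <- order(vapply(splits, length, integer(1)))
  splits <- splits[ord]; supp <- supp[ord]
  ns <- length(splits)
  parent <- rep(0L, ns)  # 0 = root
  if (ns > 1) {
    for (i in seq_len(ns - 1)) {
      for (j in (i + 1):ns) {
        if (all(splits[[i]] %in% splits[[j]])) { parent[i] <- j; break }
      }
    }
  }
  build <- function(node) {
    kids <- which(parent == node)
    if (node == 0L) {
      members <- setdiff(labs, ref)
      lab_txt <- ""
    } else {
      members <- splits[[node]]
      lab_txt <- sprintf("%g", 100 * supp[node])
    }
    covered <- unique(unlist(splits[kids]))
    leaves <- setdiff(members, covered)
    parts <- c(vapply(kids, build, character(1)), leaves)
    if (node == 0L) parts <- c(parts, ref)
    paste0("(", paste(parts, collapse = ","), ")", lab_txt)
  }
  nwk <- paste0(build(0L), ";")
  out <- ape::read.tree(text = nwk)
  out
}
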