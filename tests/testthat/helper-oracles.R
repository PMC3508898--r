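# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive enumeration, never by calling the code paths they check.

# --- tandem repeats ---------------------------------------------------------

# Majority consensus of a list of equal-length character vectors, ties to
# the first vector's residue (recomputed from scratch each call).
oracle_consensus <- function(copies) {
  u <- length(copies[[1]])
  sapply(seq_len(u), function(j) {
    col <- sapply(copies, `[`, j)
    tab <- sort(table(col), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1]]
    if (length(winners) == 1) winners else col[1]
  })
}

# All candidate arrays by direct enumeration over (start, unit_len),
# recomputing the running consensus from the full copy list at every step.
oracle_repeat_candidates <- function(region, unit_range, min_identity) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  out <- list()
  for (u in unit_range[1]:unit_range[2]) {
    if (2 * u > n) next
    for (s in 1:(n - 2 * u + 1)) {
      copies <- list(ch[s:(s + u - 1)])
      repeat {
        nxt <- s + length(copies) * u
        if (nxt + u - 1 > n) break
        cand <- ch[nxt:(nxt + u - 1)]
        cons <- oracle_consensus(copies)
        if (sum(cand == cons) / u < min_identity) break
        copies <- c(copies, list(cand))
      }
      if (length(copies) >= 2) {
        cons <- oracle_consensus(copies)
        ident <- sapply(copies, function(cp) sum(cp == cons) / u)
        out[[length(out) + 1]] <- data.frame(
          start = s, unit_len = u, n_copies = length(copies),
          mean_identity = mean(ident),
          unit_consensus = paste(cons, collapse = ""))
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

oracle_repeats <- function(region, unit_range = c(5, 10), min_identity = 0.7) {
  df <- oracle_repeat_candidates(region, unit_range, min_identity)
  if (is.null(df)) {
    return(data.frame(start = integer(), unit_len = integer(), n_copies = integer(),
                      mean_identity = numeric(), unit_consensus = character()))
  }
  df$span <- df$n_copies * df$unit_len
  df <- df[order(-df$span, df$start, df$unit_len), ]
  occ <- rep(FALSE, nchar(region))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:(df$start[i] + df$span[i] - 1)
    if (!any(occ[idx])) { occ[idx] <- TRUE; keep[i] <- TRUE }
  }
  df <- df[keep, ]
  df <- df[order(df$start), c("start", "unit_len", "n_copies", "mean_identity", "unit_consensus")]
  rownames(df) <- NULL
  df
}

# --- CaaX / transferase -----------------------------------------------------

# Lookup-table oracle for the transferase call, written as an explicit map.
oracle_transferase <- function(x_residue) {
  map <- c(L = "PGGT-I", I = "PGGT-I",
           M = "PFT", Q = "PFT", A = "PFT", C = "PFT", S = "PFT")
  out <- unname(map[x_residue])
  out[is.na(out)] <- "ambiguous"
  out
}

# --- neighbor joining -------------------------------------------------------

# Least-squares branch lengths for a fixed topology: design matrix with one
# row per taxon pair, one column per edge, 1 where the edge lies on the path.
ls_fit_tree <- function(topo, D) {
  tips <- topo$tip.label
  n <- length(tips)
  pairs <- t(combn(n, 2))
  nodepaths <- ape::nodepath(topo)  # tip -> root paths on a rooted copy
  # edge on path between tips i and j: edges whose child is in exactly one path
  edge_child <- topo$edge[, 2]
  X <- matrix(0, nrow(pairs), nrow(topo$edge))
  y <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pi <- nodepaths[[i]]; pj <- nodepaths[[j]]
    onpath <- setdiff(union(pi, pj), intersect(pi, pj))
    X[r, ] <- as.numeric(edge_child %in% onpath)
    y[r] <- D[tips[i], tips[j]]
  }
  fit <- stats::lsfit(X, y, intercept = FALSE)
  list(lengths = fit$coefficients, resid = sum(fit$residuals^2))
}

# Enumerate all unrooted topologies for the taxa of D; return the one(s)
# fitting D additively (zero residual, nonnegative lengths).
oracle_additive_tree <- function(D) {
  tips <- rownames(D)
  topos <- phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
  best <- NULL; best_res <- Inf
  for (i in seq_along(topos)) {
    topo <- topos[[i]]  # [[ attaches the shared tip labels of a multiPhylo
    f <- ls_fit_tree(topo, D)
    if (f$resid < best_res) {
      best_res <- f$resid
      topo$edge.length <- pmax(f$lengths, 0)
      best <- topo
    }
  }
  list(tree = best, resid = best_res)
}

# --- bipartition support ----------------------------------------------------

# Independent monophyly check: root each replicate at a taxon outside the
# group and ask ape whether the group is a clade.
oracle_group_support <- function(trees, taxa) {
  hits <- vapply(trees, function(tr) {
    out <- setdiff(tr$tip.label, taxa)[1]
    rt <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    ape::is.monophyletic(rt, taxa)
  }, logical(1))
  mean(hits)
}

# Random protein-ish string over the 20 amino-acid letters.
random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE), collapse = "")
}
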