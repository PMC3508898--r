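test_that("central-domain extraction keeps the contact columns and clips at edges", {
  co <- make_cohort(synth_config(seed = 5, n_per_type = c(A = 4, B = 4, C = 4)))
  cd <- extract_central_domain(co$alignment)
  win <- attr(cd, "window")
  off <- attr(co$alignment, "template_offset")
  # all seven Gbeta-contact columns fall inside the window
  contacts <- off + as.integer(names(gg_template()$conserved))
  expect_true(all(contacts >= win["from"] & contacts <= win["to"]))

  # anchor near the alignment start clips the window at column 1
  tiny <- as_alignment(tibble::tibble(id = c("a", "b"),
                                      aseq = c("DPLLKKRRWW", "DPLLKKRRWA")))
  cdt <- extract_central_domain(tiny)
  expect_equal(attr(cdt, "window")[["from"]], 1L)

  # rows without an anchor are dropped with a warning; all-anchorless errors
  mixed <- as_alignment(tibble::tibble(id = c("ok", "no"),
                                       aseq = c("DPLLKKRRWW", "AAAAKKRRWW")))
  expect_warning(cd2 <- extract_central_domain(mixed), "no")
  expect_equal(cd2$id, "ok")
  none <- as_alignment(tibble::tibble(id = "no", aseq = "AAAAKKRRWW"))
  expect_error(suppressWarnings(extract_central_domain(none)), "anchor")
})

test_that("p-distances use pairwise deletion and X never matches", {
  aln <- tibble::tibble(id = c("a", "b"), aseq = c("AAAA", "AAAV"))
  D <- seq_distances(aln, model = "p")
  expect_equal(D["a", "b"], 0.25)
  expect_equal(diag(D), c(a = 0, b = 0))

  same <- tibble::tibble(id = c("a", "b"), aseq = c("KWIL", "KWIL"))
  expect_equal(seq_distances(same, model = "p")["a", "b"], 0)

  # poisson correction closed form
  Dp <- seq_distances(aln, model = "poisson")
  expect_equal(Dp["a", "b"], -log(0.75))

  # gap columns drop out of the pair's denominator; X mismatches even X
  gx <- tibble::tibble(id = c("a", "b"), aseq = c("A-XX", "AAXA"))
  Dg <- seq_distances(gx, model = "p")
  expect_equal(Dg["a", "b"], 2 / 3)

  allgap <- tibble::tibble(id = c("a", "b", "c"), aseq = c("AA--", "--AA", "AAAA"))
  expect_error(seq_distances(allgap), "no comparable.*a.*b")
})

test_that("three taxa give the closed-form star", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 1, c = 3))
})

test_that("neighbor joining recovers additive matrices exactly (enumeration oracle)", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (n in 4:6) {
    for (rep in 1:3) {
      tr <- ape::rtree(n, rooted = FALSE)
      tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
      D <- ape::cophenetic.phylo(tr)
      D <- D[sort(rownames(D)), sort(colnames(D))]
      got <- nj_tree(D)
      oracle <- oracle_additive_tree(D)
      expect_lt(oracle$resid, 1e-20)
      expect_equal(as.numeric(ape::dist.topo(got, oracle$tree)), 0)
      # path lengths reproduce the input matrix
      expect_equal(max(abs(ape::cophenetic.phylo(got)[rownames(D), colnames(D)] - D)), 0,
                   tolerance = 1e-8)
    }
  }
})

test_that("nj_tree agrees with ape::nj on random noisy matrices", {
  set.seed(23)
  for (rep in 1:4) {
    n <- sample(5:9, 1)
    M <- matrix(stats::runif(n * n, 0.1, 1), n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    expect_equal(as.numeric(ape::dist.topo(nj_tree(D), ape::nj(D))), 0)
  }
})

test_that("negative NJ branch estimates are floored with the deficit moved to the sister", {
  # matrix engineered to produce a negative pair branch
  D <- matrix(c(0, 0.1, 1, 1,
                0.1, 0, 1.4, 1.4,
                1, 1.4, 0, 0.2,
                1, 1.4, 0.2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  # pairwise path length for the joined pair is preserved
  ct <- ape::cophenetic.phylo(tr)
  expect_equal(ct["a", "b"], 0.1, tolerance = 1e-8)
})

test_that("bootstrap supports are deterministic and verified by an independent count", {
  co <- make_cohort(synth_config(seed = 29, n_per_type = c(A = 5, B = 5, C = 5),
                                 divergence = 0.05, type_divergence = 0.4))
  cd <- extract_central_domain(co$alignment)
  grp <- data.frame(id = co$truth$id, group = co$truth$true_type)
  b1 <- bootstrap_support(cd, grp, n_replicates = 40, seed = 101)
  b2 <- bootstrap_support(cd, grp, n_replicates = 40, seed = 101)
  expect_identical(b1$support, b2$support)
  b3 <- bootstrap_support(cd, grp, n_replicates = 40, seed = 102)
  expect_equal(nrow(b3$support), 3)

  # recount support for each group from the stored replicate trees via
  # an independent rooted-monophyly route
  for (g in c("A", "B", "C")) {
    taxa <- grp$id[grp$group == g]
    expect_equal(b1$support$support[b1$support$group == g],
                 oracle_group_support(b1$replicate_trees, taxa))
  }
})

test_that("undefined groups (too small or too large) report NA support, not zero", {
  aln <- as_alignment(tibble::tibble(
    id = letters[1:5],
    aseq = c("KWILKWILAA", "KWILKWILAV", "RRRRRRRRAA", "RRRRRRRRAV", "RRRRRRRRVV")))
  grp <- data.frame(id = letters[1:5], group = c("one", "big", "big", "big", "big"))
  bs <- bootstrap_support(aln, grp, n_replicates = 10, seed = 3)
  expect_true(is.na(bs$support$support[bs$support$group == "one"]))
  expect_true(is.na(bs$support$support[bs$support$group == "big"]))
})

test_that("duplicating every column leaves the point NJ topology unchanged", {
  co <- make_cohort(synth_config(seed = 41, n_per_type = c(A = 3, B = 3, C = 3)))
  cd <- extract_central_domain(co$alignment)
  t1 <- nj_tree(seq_distances(cd))
  doubled <- as_alignment(dplyr::mutate(cd, aseq = paste0(aseq, aseq)))
  t2 <- nj_tree(seq_distances(doubled))
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("strict majority-rule consensus keeps splits only above the threshold", {
  t_ab <- ape::read.tree(text = "((a,b),c,d);")
  t_ac <- ape::read.tree(text = "((a,c),b,d);")

  same <- majority_consensus(rep(list(t_ab), 10))
  expect_equal(as.numeric(ape::dist.topo(same, t_ab)), 0)
  expect_true("100" %in% same$node.label)

  sixty <- majority_consensus(c(rep(list(t_ab), 6), rep(list(t_ac), 4)))
  expect_equal(as.numeric(ape::dist.topo(sixty, t_ab)), 0)
  expect_true("60" %in% sixty$node.label)

  # two incompatible splits at exactly 50% each: neither is retained
  fifty <- majority_consensus(c(rep(list(t_ab), 5), rep(list(t_ac), 5)))
  expect_equal(fifty$Nnode, 1)  # star

  expect_error(majority_consensus(list(t_ab, ape::read.tree(text = "((a,b),c,e);"))),
               "leaf sets")
})

test_that("majority consensus agrees with ape on a clear-majority case", {
  set.seed(8)
  base <- ape::rtree(7, rooted = FALSE)
  other <- ape::rtree(7, rooted = FALSE)
  trees <- c(rep(list(base), 8), rep(list(other), 2))
  class(trees) <- "multiPhylo"
  mine <- majority_consensus(trees)
  apes <- ape::consensus(trees, p = 0.5)
  expect_equal(as.numeric(ape::dist.topo(mine, apes)), 0)
})
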