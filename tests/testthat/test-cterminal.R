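test_that("find_anchor matches [DE]PL[LI], first occurrence, absence is NA", {
  expect_equal(find_anchor("MMDPLLKK"), tibble::tibble(anchor_start = 3L, anchor_end = 6L))
  expect_equal(find_anchor("MMEPLIKK"), tibble::tibble(anchor_start = 3L, anchor_end = 6L))
  expect_true(is.na(find_anchor("MMMM")$anchor_start))
  # first match wins
  expect_equal(find_anchor("DPLLAAADPLL")$anchor_start, 1L)
})

test_that("detect_caax requires the cysteine exactly at -4 and flags the -6 cysteine", {
  r <- detect_caax(paste0(random_aa(20), "CGCSIL"))
  expect_equal(r$caax, "CSIL")
  expect_equal(r$prenyl_site, -4L)
  expect_equal(r$sacyl_site, -6L)

  expect_true(is.na(detect_caax(paste0(random_aa(20), "KGSDFS"))$caax))

  # minimal length: a bare CaaX has no -6 position
  r4 <- detect_caax("CLIL")
  expect_equal(r4$caax, "CLIL")
  expect_equal(r4$prenyl_site, -4L)
  expect_true(is.na(r4$sacyl_site))

  # a cysteine elsewhere is not a CaaX: motif must be terminal
  expect_true(is.na(detect_caax("CAAXAA")$caax))
  expect_error(detect_caax("CSI"), "shorter than 4")
})

test_that("transferase call uses only the X residue with disjoint preference sets", {
  expect_equal(predict_transferase("CWIL"), "PGGT-I")
  expect_equal(predict_transferase("CVVM"), "PFT")
  expect_equal(predict_transferase("CAAG"), "ambiguous")
  expect_error(predict_transferase("WIL"), "malformed")
  expect_true(is.na(predict_transferase(NA_character_)))
})

test_that("caax detection and transferase calls match exhaustive suffix enumeration", {
  # all 20^3 a1-a2-X suffixes behind a fixed -4 cysteine
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  grid <- expand.grid(a1 = aa, a2 = aa, x = aa, stringsAsFactors = FALSE)
  seqs <- paste0("MKDPLLRT", "C", grid$a1, grid$a2, grid$x)
  det <- detect_caax(seqs)
  expect_true(all(det$prenyl_site == -4L))
  expect_equal(det$caax, paste0("C", grid$a1, grid$a2, grid$x))
  expect_equal(predict_transferase(det$caax), oracle_transferase(grid$x))
  # the same suffixes shifted off the terminus are never CaaX
  expect_true(all(is.na(detect_caax(paste0(seqs, "K"))$caax[grid$a1 != "C"])))
})

test_that("anchor_composition counts residue classes over the C-terminal window", {
  r <- anchor_composition("SRQAKRWI", window = 8)
  expect_equal(r$frac_basic, 3 / 8)
  expect_equal(r$frac_aromatic, 1 / 8)
  expect_equal(r$frac_hydrophobic, 1 / 8)
  expect_true(r$enriched_basic)

  z <- anchor_composition("AAAAAAAA", window = 8)
  expect_equal(unlist(z[1, 1:3]), c(frac_basic = 0, frac_aromatic = 0, frac_hydrophobic = 0))

  k <- anchor_composition(strrep("K", 30), window = 25)
  expect_equal(k$frac_basic, 1)
  expect_true(k$enriched_basic)
})

test_that("cys_fraction is the plain cysteine proportion", {
  expect_equal(cys_fraction("CCCCC"), 1)
  expect_equal(cys_fraction("ACDEF"), 0.2)
  tail100 <- paste0(strrep("C", 19), strrep("A", 81))
  expect_equal(cys_fraction(tail100), 0.19)
  expect_error(cys_fraction(""), "empty")
})

test_that("classify_gg reproduces the three canonical architectures", {
  tpl <- gg_template()$seq
  seq_a <- agg2_like()
  seq_b <- paste0(strrep("N", 20), tpl, strrep("QTA", 6), "SRQAKRWI")
  tail_c <- paste0(strrep("CAK", 50))  # 150 aa at 1/3 cysteine
  seq_c <- paste0(strrep("N", 35), tpl, tail_c)
  calls <- classify_gg(tibble::tibble(id = c("a", "b", "c"),
                                      seq = c(seq_a, seq_b, seq_c)))
  expect_equal(calls$label, c("A", "B", "C"))
  expect_equal(calls$caax[1], "CSIL")
  expect_equal(calls$prenyl_site[1], -4L)
  expect_equal(calls$sacyl_site[1], -6L)
  expect_true(calls$cys_free_window[2])
  expect_gte(calls$tail_len[3], 50)
  expect_gte(calls$cys_frac_tail[3], 0.15)
  # no anchor -> unclassified
  expect_equal(classify_gg(tibble::tibble(id = "u", seq = "MMMMKKKK"))$label, "unclassified")
})

test_that("type calls are mutually exclusive, order-independent, and evidence re-checks", {
  co <- make_cohort(synth_config(seed = 11, n_per_type = c(A = 6, B = 6, C = 6)))
  calls <- classify_gg(co$records)
  perm <- sample(nrow(co$records))
  calls_perm <- classify_gg(co$records[perm, ])
  expect_equal(calls_perm$label, calls$label[perm])
  # re-check evidence against the raw sequences
  for (i in seq_len(nrow(calls))) {
    s <- co$records$seq[i]
    if (calls$label[i] == "A") expect_equal(substr(s, nchar(s) - 3, nchar(s) - 3), "C")
    if (calls$label[i] == "B") {
      expect_false(grepl("C", substr(s, nchar(s) - 24, nchar(s)), fixed = TRUE))
    }
    if (calls$label[i] == "C") {
      tail <- substr(s, calls$anchor_end[i] + 1, nchar(s))
      expect_gte(nchar(tail), 50)
      expect_gte(cys_fraction(tail), 0.15)
    }
  }
})

test_that("gbeta contact validation reports exactly the failing template positions", {
  tpl <- gg_template()
  cmap <- stats::setNames(as.integer(names(tpl$conserved)), names(tpl$conserved))
  aln <- tibble::tibble(id = c("wt", "p52a"),
                        aseq = c(tpl$seq, paste0(substr(tpl$seq, 1, 51), "A", substr(tpl$seq, 53, 60))))
  chk <- validate_gbeta_contacts(aln, cmap)
  expect_true(all(chk$ok[chk$id == "wt"]))
  bad <- chk[!chk$ok, ]
  expect_equal(bad$id, "p52a")
  expect_equal(bad$template_pos, 52L)
  expect_error(validate_gbeta_contacts(aln, cmap[-1]), "lacks template position")
})

test_that("nomenclature names follow the species-initials + GG + type + ordinal scheme", {
  calls <- tibble::tibble(
    id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    species = c("Arabidopsis thaliana", "Oryza sativa", "Oryza sativa",
                "Oryza sativa", "Oryza sativa", "Arabidopsis thaliana"),
    label = c("A", "C", "C", "C", "B", "unclassified")
  )
  nm <- assign_names(calls)
  expect_equal(nm$new_name, c("AtGGA1", "OsGGC1", "OsGGC2", "OsGGC3", "OsGGB1", NA))
  expect_error(assign_names(tibble::tibble(id = "q", species = "", label = "A")), "q")
})
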