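#' Locate the DPLL/I central-domain anchor
#'
#' Finds the first occurrence of the conserved `[DE]-P-L-[LI]` block that
#' marks the C-terminal end of the Ggamma central domain. The first match
#' wins; absence is reported as `NA`, not an error.
#'
#' @param seq Character vector of protein sequences.
#' @return A tibble with one row per sequence: `anchor_start`,
#'   `anchor_end` (1-based, inclusive; `NA` when no anchor is found).
#' @examples
#' find_anchor(c("MMDPLLKK", "MMMM"))
#' @export
find_anchor <- function(seq) {
  seq <- pull_seqs(seq)
  if (any(!nzchar(seq))) stop_gt("empty sequence passed to find_anchor()")
  m <- regexpr("[DE]PL[LI]", seq)
  start <- unname(ifelse(m == -1L, NA_integer_, as.integer(m)))
  tibble(anchor_start = start, anchor_end = start + 3L)
}

#' Detect a terminal CaaX box and its lipidation sites
#'
#' A CaaX box is called when the cysteine sits exactly four residues from
#' the end of the protein (the motif must be terminal). Positions are
#' reported as negative indices counted from the C-terminal residue
#' (`-1` = last residue): the prenylatable cysteine is at `-4`. When a
#' second cysteine sits at `-6` — the conserved "two cysteines separated
#' by one amino acid" arrangement of dual-lipidated tails such as ...CGCSIL —
#' it is reported as the S-acylation candidate.
#'
#' @param seq Character vector of protein sequences, each at least 4
#'   residues long.
#' @return A tibble with one row per sequence: `caax` (the terminal four
#'   residues, or `NA`), `prenyl_site` (`-4` or `NA`), `sacyl_site`
#'   (`-6` or `NA`).
#' @examples
#' detect_caax("MAREVQKDPLLCGCSIL")
#' @export
detect_caax <- function(seq) {
  seq <- pull_seqs(seq)
  n <- nchar(seq)
  if (any(n < 4)) {
    stop_gt("sequence(s) shorter than 4 residues: cannot test for a CaaX box")
  }
  last4 <- substr(seq, n - 3L, n)
  has <- substr(last4, 1L, 1L) == "C"
  at6 <- n >= 6L & substr(seq, n - 5L, n - 5L) == "C"
  tibble(
    caax = unname(ifelse(has, last4, NA_character_)),
    prenyl_site = unname(ifelse(has, -4L, NA_integer_)),
    sacyl_site = unname(ifelse(has & at6, -6L, NA_integer_))
  )
}

#' Predict the prenyltransferase from the CaaX X residue
#'
#' Protein farnesyltransferase (PFT) prefers CaaX boxes whose X residue is
#' methionine, glutamine, alanine, cysteine or serine; protein
#' geranylgeranyltransferase type I (PGGT-I) prefers leucine or isoleucine.
#' Only X is used; the two preference sets are disjoint, so a call is never
#' dual. Any other X residue is `"ambiguous"`.
#'
#' @param caax Character vector of 4-residue CaaX strings beginning with
#'   `C` (`NA` allowed, propagated).
#' @return Character vector over `{"PFT", "PGGT-I", "ambiguous"}` (with
#'   `NA` for `NA` input).
#' @examples
#' predict_transferase(c("CWIL", "CVVM", "CAAG"))
#' @export
predict_transferase <- function(caax) {
  ok <- is.na(caax) | (nchar(caax) == 4L & substr(caax, 1L, 1L) == "C")
  if (any(!ok)) {
    stop_gt("malformed CaaX string(s): %s", paste(caax[!ok], collapse = ", "))
  }
  x <- substr(caax, 4L, 4L)
  out <- rep(NA_character_, length(caax))
  out[!is.na(x) & x %in% c("L", "I")] <- "PGGT-I"
  out[!is.na(x) & x %in% c("M", "Q", "A", "C", "S")] <- "PFT"
  out[!is.na(x) & is.na(out)] <- "ambiguous"
  out
}

#' C-terminal residue-class composition
#'
#' Fractions of basic (K/R), aromatic (W/F) and strongly hydrophobic (I/L)
#' residues over the last `window` residues — the composition that turns a
#' non-prenylated C-terminus into a polybasic membrane anchor. Each class
#' also gets an enrichment flag: fraction above the uniform background
#' (class size / 20).
#'
#' @param seq Character vector of protein sequences.
#' @param window Window length in residues (counted from the C-terminus;
#'   shorter sequences use their full length). Default 25.
#' @return A tibble: `frac_basic`, `frac_aromatic`, `frac_hydrophobic`,
#'   `enriched_basic`, `enriched_aromatic`, `enriched_hydrophobic`.
#' @examples
#' anchor_composition("SRQAKRWI", window = 8)
#' @export
anchor_composition <- function(seq, window = 25) {
  seq <- pull_seqs(seq)
  if (window < 1) stop_gt("window must be >= 1")
  n <- nchar(seq)
  w <- pmin(as.integer(window), n)
  tail <- substr(seq, n - w + 1L, n)
  count_class <- function(s, cls) {
    vapply(strsplit(s, "", fixed = TRUE), function(ch) sum(ch %in% cls), numeric(1))
  }
  fb <- count_class(tail, AA_BASIC) / w
  fa <- count_class(tail, AA_AROMATIC) / w
  fh <- count_class(tail, AA_HYDROPHOBIC) / w
  tibble(
    frac_basic = unname(fb), frac_aromatic = unname(fa), frac_hydrophobic = unname(fh),
    enriched_basic = unname(fb > length(AA_BASIC) / 20),
    enriched_aromatic = unname(fa > length(AA_AROMATIC) / 20),
    enriched_hydrophobic = unname(fh > length(AA_HYDROPHOBIC) / 20)
  )
}

#' Cysteine fraction of a region
#'
#' @param region Character vector of non-empty sequence regions.
#' @return Numeric vector: count of `C` over region length, in `[0, 1]`.
#' @examples
#' cys_fraction("ACDEF")
#' @export
cys_fraction <- function(region) {
  region <- pull_seqs(region)
  if (any(!nzchar(region) | is.na(region))) stop_gt("cys_fraction() of an empty region")
  n <- nchar(region)
  unname((n - nchar(gsub("C", "", region, fixed = TRUE))) / n)
}

#' Classify Ggamma sequences into structural types A, B and C
#'
#' The core structural classification. For each sequence: (1) locate the
#' `[DE]PL[LI]` central-domain anchor — no anchor means `unclassified`;
#' (2) take the tail after the anchor; (3) a long, cysteine-rich tail
#' (`tail_len >= l_c` and cysteine fraction `>= c_min`) is type C — this
#' test pre-empts the CaaX test because about half of the long cysteine-rich
#' tails also end in a CaaX-like motif; (4) otherwise a terminal CaaX box is
#' type A; (5) otherwise a C-terminus with no cysteine in the last `window`
#' residues is type B; (6) anything else is `unclassified`.
#'
#' Every threshold comparison used for the call is kept as an evidence
#' column, so a call can be re-checked against the sequence.
#'
#' @param data A data frame with columns `id` and `seq` (optionally
#'   `species`, `group`), e.g. from [read_fasta()] or [make_cohort()].
#' @param l_c Minimum tail length (residues after the anchor) for type C.
#'   Default 50, leaving margin under the ~70-residue minimum extension
#'   observed in plants.
#' @param c_min Minimum cysteine fraction of the tail for type C. Default
#'   0.15, under the observed 19% lower bound.
#' @param window Length of the C-terminal window that must be cysteine-free
#'   for type B, and of the composition window. Default 25.
#' @return A tibble, one row per input record: `id`, `species`, `group`,
#'   `label` (`"A"`, `"B"`, `"C"` or `"unclassified"`), anchor span, tail
#'   statistics, CaaX/lipidation calls, transferase prediction and
#'   composition fractions. The thresholds used are stored in the
#'   `params_used` attribute.
#' @examples
#' co <- make_cohort(synth_config(seed = 1, n_per_type = c(A = 2, B = 2, C = 2)))
#' classify_gg(co$records)
#' @export
classify_gg <- function(data, l_c = 50, c_min = 0.15, window = 25) {
  seqs <- pull_seqs(data)
  n <- nchar(seqs)
  anc <- find_anchor(seqs)
  tail <- ifelse(is.na(anc$anchor_end), NA_character_,
                 substr(seqs, anc$anchor_end + 1L, n))
  tail_len <- ifelse(is.na(tail), NA_integer_, nchar(tail))
  cys_frac_tail <- ifelse(is.na(tail) | tail_len == 0L, NA_real_,
                          vapply(seq_along(tail), function(i) {
                            if (is.na(tail[i]) || tail_len[i] == 0L) return(NA_real_)
                            cys_fraction(tail[i])
                          }, numeric(1)))

  cx <- detect_caax(ifelse(n >= 4L, seqs, strrep("A", 4L)))
  cx[n < 4L, ] <- tibble(caax = NA_character_, prenyl_site = NA_integer_,
                         sacyl_site = NA_integer_)

  w <- pmin(as.integer(window), n)
  last_w <- substr(seqs, n - w + 1L, n)
  cys_free_window <- !grepl("C", last_w, fixed = TRUE)

  is_c <- !is.na(tail_len) & tail_len >= l_c &
    !is.na(cys_frac_tail) & cys_frac_tail >= c_min
  is_a <- !is_c & !is.na(anc$anchor_start) & !is.na(cx$caax)
  is_b <- !is_c & !is_a & !is.na(anc$anchor_start) & cys_free_window
  label <- rep("unclassified", length(seqs))
  label[is_c] <- "C"
  label[is_a] <- "A"
  label[is_b] <- "B"

  comp <- anchor_composition(seqs, window = window)
  out <- tibble(
    id = if (is.data.frame(data) && "id" %in% names(data)) data$id else names(seqs) %||% as.character(seq_along(seqs)),
    species = if (is.data.frame(data) && "species" %in% names(data)) data$species else "",
    group = if (is.data.frame(data) && "group" %in% names(data)) data$group else "",
    label = label,
    anchor_start = anc$anchor_start,
    anchor_end = anc$anchor_end,
    tail_len = unname(tail_len),
    cys_frac_tail = unname(cys_frac_tail),
    caax = cx$caax,
    prenyl_site = cx$prenyl_site,
    sacyl_site = cx$sacyl_site,
    transferase = ifelse(is.na(cx$caax), "none", predict_transferase(cx$caax)),
    cys_free_window = unname(cys_free_window)
  )
  out <- dplyr::bind_cols(out, comp)
  attr(out, "params_used") <- list(l_c = l_c, c_min = c_min, window = window)
  class(out) <- c("gg_typecalls", class(out))
  out
}

# Template coordinate system: the seven residues whose hydrogen bonds and
# hydrophobic contacts hold the Gbeta interaction together.
GBETA_CONTACTS <- list(
  `12` = c("L", "V"), `25` = "E", `36` = "S",
  `51` = c("D", "E"), `52` = "P", `53` = "L", `54` = c("L", "I")
)

#' Check the conserved Gbeta-contact residues
#'
#' Verifies, for every aligned record, the seven central-domain residues
#' that mediate the Ggamma-Gbeta interaction (template positions 12 (L/V),
#' 25 (E), 36 (S), 51 (D/E), 52 (P), 53 (L), 54 (L/I)). Records are checked
#' at the alignment columns given by `column_map`.
#'
#' @param alignment An alignment tibble (columns `id`, `aseq`).
#' @param column_map Named integer vector mapping each template position
#'   (`"12"`, `"25"`, ...) to an alignment column; must cover all seven.
#' @return A tibble with one row per (record, template position): `id`,
#'   `template_pos`, `column`, `residue`, `ok`. Filter on `!ok` for the
#'   missing contacts.
#' @export
validate_gbeta_contacts <- function(alignment, column_map) {
  need <- names(GBETA_CONTACTS)
  have <- names(column_map)
  missing <- setdiff(need, have)
  if (length(missing) > 0) {
    stop_gt("column_map lacks template position(s): %s", paste(missing, collapse = ", "))
  }
  m <- alignment_matrix(as_alignment(alignment))
  rows <- purrr::map_dfr(need, function(p) {
    col <- column_map[[p]]
    if (col < 1 || col > ncol(m)) stop_gt("column %d for template position %s is outside the alignment", col, p)
    res <- m[, col]
    tibble(id = rownames(m), template_pos = as.integer(p), column = as.integer(col),
           residue = unname(res), ok = unname(res %in% GBETA_CONTACTS[[p]]))
  })
  rows
}

#' Assign type-based nomenclature names
#'
#' Builds names of the form `AtGGA1`: uppercase genus initial, lowercase
#' species-epithet initial, `GG`, the structural type letter, and an
#' ordinal within each (species, type) pair, numbered in input order
#' starting at 1. Unclassified records get no name (`NA`).
#'
#' @param typecalls Output of [classify_gg()] (needs `id`, `species`,
#'   `label`).
#' @return A tibble with columns `old_id`, `new_name`.
#' @examples
#' calls <- tibble::tibble(id = "x1", species = "Arabidopsis thaliana", label = "A")
#' assign_names(calls)
#' @export
assign_names <- function(typecalls) {
  sp <- typecalls$species
  bad <- is.na(sp) | !nzchar(trimws(sp))
  if (any(bad)) {
    stop_gt("record(s) without a species, cannot name: %s",
            paste(typecalls$id[bad], collapse = ", "))
  }
  parts <- strsplit(trimws(sp), "[ \t]+")
  prefix <- vapply(parts, function(p) {
    if (length(p) < 2) stop_gt("species '%s' is not a binomial", paste(p, collapse = " "))
    paste0(toupper(substr(p[1], 1, 1)), tolower(substr(p[2], 1, 1)))
  }, character(1))
  df <- tibble(old_id = typecalls$id, species = sp, label = typecalls$label,
               prefix = prefix, .ord = seq_len(nrow(typecalls)))
  named <- df$label %in% c("A", "B", "C")
  df$new_name <- NA_character_
  if (any(named)) {
    sub <- df[named, ]
    sub <- dplyr::mutate(
      dplyr::group_by(sub, .data$species, .data$label),
      k = rank(.data$.ord, ties.method = "first")
    )
    sub <- dplyr::ungroup(sub)
    df$new_name[named] <- paste0(sub$prefix, "GG", sub$label, sub$k)
  }
  dplyr::select(df, "old_id", "new_name")
}
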