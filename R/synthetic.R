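# Fixed 60-residue central-domain template. The seven Gbeta-contact
# residues sit at their template coordinates (12 L, 25 E, 36 S, 51 D,
# 52 P, 53 L, 54 L) and the [DE]PL[LI] anchor occupies 51-54; the
# template is cysteine-free and contains no proline outside position 52,
# so no spurious anchor can pre-date the real one.
CENTRAL_TEMPLATE <- "MAREVQKLNSVLREKAGIMNRTFVELQNKARDMVGSHLATKVENMRAGFKDPLLVGRAKT"

TYPE_A_ENDINGS <- c("CRCWIL", "CGCSIL", "CLIL", "CSIL")
TYPE_A_ENDING_PROBS <- c(0.4, 0.2, 0.2, 0.2)

SPECIES_POOLS <- list(
  eudicot = c("Arabidopsis thaliana", "Gossypium raimondii", "Carica papaya",
              "Brassica rapa", "Glycine max"),
  monocot = c("Oryza sativa", "Zea mays", "Triticum aestivum"),
  gymnosperm = c("Pinus taeda", "Picea abies")
)

#' The central-domain template
#'
#' @return A list: `seq` (the 60-residue template), `conserved` (named
#'   list of Gbeta-contact positions and their allowed residues),
#'   `anchor` (template span of the `[DE]PL[LI]` anchor).
#' @export
gg_template <- function() {
  list(seq = CENTRAL_TEMPLATE,
       conserved = GBETA_CONTACTS,
       anchor = c(51L, 54L))
}

#' Configuration for the synthetic Ggamma cohort generator
#'
#' Defaults encode the C-terminal architectures and gene structures the
#' classification is built around: N-termini of 10-75 residues; type A
#' tails ending in a CaaX box (CRCWIL most often, with the CGCSIL /
#' CLIL / CSIL variants); type B tails of 25-40 cysteine-free residues
#' ending in the eudicot SRxxKRWI or monocot KGSDFS consensus; type C
#' cysteine-rich extensions of 70-350 residues at a 19-38% cysteine
#' fraction; 4 exons for type A/B genes and 5 for type C.
#'
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param n_per_type Named counts for types A, B, C.
#' @param divergence Within-type per-position substitution probability at
#'   non-conserved central-domain positions. Default 0.1.
#' @param type_divergence Between-type divergence: probability that a
#'   non-conserved template position is substituted in a type's own
#'   central-domain template. Default 0.3.
#' @param nterm_len_range,tailA_linker_range,tailB_len_range,tailC_len_range
#'   Inclusive integer ranges for segment lengths (residues).
#' @param tailC_cys_range Range of the type C tail cysteine fraction.
#' @param typeB_dialect `"mixed"` (eudicot/monocot endings 50/50),
#'   `"eudicot"`, or `"monocot"`.
#' @param repeat_spec Optional list `list(unit_len =, n_copies =)` to
#'   plant a perfect tandem repeat in every type C tail.
#' @param intron_len_range Range of intron lengths for synthetic gene
#'   models (nucleotides).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         n_per_type = c(A = 8, B = 8, C = 8),
                         divergence = 0.1,
                         type_divergence = 0.3,
                         nterm_len_range = c(10, 75),
                         tailA_linker_range = c(6, 16),
                         tailB_len_range = c(25, 40),
                         tailC_len_range = c(70, 350),
                         tailC_cys_range = c(0.19, 0.38),
                         typeB_dialect = c("mixed", "eudicot", "monocot"),
                         repeat_spec = NULL,
                         intron_len_range = c(80, 500)) {
  typeB_dialect <- match.arg(typeB_dialect)
  if (divergence < 0 || divergence > 1) stop_gt("divergence must be in [0, 1]")
  if (type_divergence < 0 || type_divergence > 1) stop_gt("type_divergence must be in [0, 1]")
  stopifnot(all(c("A", "B", "C") %in% names(n_per_type)), all(n_per_type >= 0))
  ranges <- list(nterm_len_range, tailA_linker_range, tailB_len_range,
                 tailC_len_range, tailC_cys_range, intron_len_range)
  if (any(vapply(ranges, function(r) length(r) != 2 || r[2] < r[1], logical(1)))) {
    stop_gt("every range must be a non-degenerate (lo, hi) pair")
  }
  if (!is.null(repeat_spec)) {
    stopifnot(is.list(repeat_spec), all(c("unit_len", "n_copies") %in% names(repeat_spec)))
  }
  structure(list(seed = seed, n_per_type = n_per_type, divergence = divergence,
                 type_divergence = type_divergence,
                 nterm_len_range = nterm_len_range,
                 tailA_linker_range = tailA_linker_range,
                 tailB_len_range = tailB_len_range,
                 tailC_len_range = tailC_len_range,
                 tailC_cys_range = tailC_cys_range,
                 typeB_dialect = typeB_dialect,
                 repeat_spec = repeat_spec,
                 intron_len_range = intron_len_range),
            class = "synth_config")
}

rand_aa <- function(n, exclude = NULL) {
  pool <- setdiff(AA20, exclude)
  sample(pool, n, replace = TRUE)
}

runif_int <- function(range) sample(range[1]:range[2], 1)

# Substitute non-conserved positions with probability `prob`; conserved
# Gbeta-contact positions are immune.
mutate_template <- function(seq, prob) {
  ch <- chars(seq)
  immune <- as.integer(names(GBETA_CONTACTS))
  for (p in setdiff(seq_along(ch), immune)) {
    if (stats::runif(1) < prob) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  }
  collapse0(ch)
}

make_tail <- function(type, config) {
  switch(type,
    A = {
      linker <- collapse0(rand_aa(runif_int(config$tailA_linker_range), exclude = "C"))
      ending <- sample(TYPE_A_ENDINGS, 1, prob = TYPE_A_ENDING_PROBS)
      list(tail = paste0(linker, ending), ending = ending, dialect = NA_character_)
    },
    B = {
      dialect <- if (config$typeB_dialect == "mixed") {
        sample(c("eudicot", "monocot"), 1)
      } else config$typeB_dialect
      suffix <- if (dialect == "eudicot") {
        paste0("SR", collapse0(rand_aa(2, exclude = "C")), "KRWI")
      } else "KGSDFS"
      len <- runif_int(config$tailB_len_range)
      prefix <- collapse0(rand_aa(max(0L, len - nchar(suffix)), exclude = "C"))
      list(tail = paste0(prefix, suffix), ending = suffix, dialect = dialect)
    },
    C = {
      len <- runif_int(config$tailC_len_range)
      frac <- stats::runif(1, config$tailC_cys_range[1], config$tailC_cys_range[2])
      n_c <- round(frac * len)
      ch <- rand_aa(len, exclude = "C")
      ch[sample.int(len, n_c)] <- "C"
      if (!is.null(config$repeat_spec)) {
        u <- config$repeat_spec$unit_len
        k <- config$repeat_spec$n_copies
        if (u * k <= len) {
          unit <- rand_aa(u, exclude = "C")
          unit[stats::runif(u) < frac] <- "C"
          s <- sample.int(len - u * k + 1L, 1)
          ch[s:(s + u * k - 1L)] <- rep(unit, k)
        }
      }
      list(tail = collapse0(ch), ending = NA_character_, dialect = NA_character_)
    },
    stop_gt("unknown type '%s'", type)
  )
}

#' Generate one synthetic Ggamma record
#'
#' Draws an N-terminal segment, a mutated copy of the central-domain
#' template (conserved positions immune) and a type-specific tail, using
#' the current RNG state. Assemblies in which a chance `[DE]PL[LI]` match
#' pre-dates the planted anchor are redrawn, so the planted anchor is
#' always the first match.
#'
#' @param type `"A"`, `"B"` or `"C"`.
#' @param config A [synth_config()].
#' @param type_template Central-domain template for this type (default:
#'   the base template).
#' @return A list: `seq`, `nterm_len`, `central`, `tail`, `ending`,
#'   `dialect`, `anchor_start`, `anchor_end`.
#' @export
make_record <- function(type, config, type_template = CENTRAL_TEMPLATE) {
  for (try in 1:200) {
    nl <- runif_int(config$nterm_len_range)
    nterm <- collapse0(rand_aa(nl))
    central <- mutate_template(type_template, config$divergence)
    tl <- make_tail(type, config)
    seq <- paste0(nterm, central, tl$tail)
    expected <- nl + 51L
    a <- find_anchor(seq)
    if (!is.na(a$anchor_start) && a$anchor_start == expected) {
      return(list(seq = seq, nterm_len = nl, central = central, tail = tl$tail,
                  ending = tl$ending, dialect = tl$dialect,
                  anchor_start = expected, anchor_end = expected + 3L))
    }
  }
  stop_gt("could not place a unique anchor after 200 draws (pathological config)")
}

#' Generate a synthetic Ggamma cohort with planted ground truth
#'
#' Builds a seeded cohort of type A, B and C records around a shared
#' central-domain template: each type first receives its own template
#' variant (non-conserved positions substituted with probability
#' `type_divergence`, giving between-type divergence), and each record
#' then mutates its type template with probability `divergence`
#' (within-type divergence). Because every record shares the template
#' coordinate system, the cohort is natively aligned: N-termini are
#' left-padded and tails right-padded with gaps.
#'
#' @param config A [synth_config()].
#' @return A `gg_cohort` list: `records` (tibble `id`, `species`, `group`,
#'   `seq`), `alignment` (alignment tibble), `truth` (tibble of planted
#'   ground truth per record), `templates` (per-type central templates),
#'   `config`.
#' @examples
#' co <- make_cohort(synth_config(seed = 7, n_per_type = c(A = 3, B = 3, C = 3)))
#' co$truth
#' @export
make_cohort <- function(config = synth_config()) {
  if (sum(config$n_per_type) == 0) stop_gt("cohort with zero sequences")
  set.seed(config$seed)
  templates <- list(
    A = mutate_template(CENTRAL_TEMPLATE, config$type_divergence),
    B = mutate_template(CENTRAL_TEMPLATE, config$type_divergence),
    C = mutate_template(CENTRAL_TEMPLATE, config$type_divergence)
  )
  rows <- list()
  for (type in c("A", "B", "C")) {
    n <- config$n_per_type[[type]]
    if (n == 0) next
    for (i in seq_len(n)) {
      rec <- make_record(type, config, templates[[type]])
      pool_name <- if (type == "B" && !is.na(rec$dialect)) rec$dialect else sample(names(SPECIES_POOLS), 1)
      species <- sample(SPECIES_POOLS[[pool_name]], 1)
      rows[[length(rows) + 1L]] <- tibble(
        id = sprintf("syn%s%03d", type, i),
        species = species,
        group = pool_name,
        true_type = type,
        seq = rec$seq,
        nterm_len = rec$nterm_len,
        central = rec$central,
        tail = rec$tail,
        tail_len = nchar(rec$tail),
        tail_cys_frac = if (nchar(rec$tail) > 0) cys_fraction(rec$tail) else NA_real_,
        ending = rec$ending,
        dialect = rec$dialect,
        anchor_start = rec$anchor_start,
        anchor_end = rec$anchor_end
      )
    }
  }
  truth <- dplyr::bind_rows(rows)
  records <- dplyr::select(truth, "id", "species", "group", "seq")
  nterm_w <- max(truth$nterm_len)
  tail_w <- max(truth$tail_len)
  aseq <- paste0(
    strrep("-", nterm_w - truth$nterm_len),
    substr(truth$seq, 1L, truth$nterm_len),
    truth$central,
    truth$tail,
    strrep("-", tail_w - truth$tail_len)
  )
  alignment <- as_alignment(tibble(id = truth$id, species = truth$species,
                                   group = truth$group, aseq = aseq))
  attr(alignment, "template_offset") <- nterm_w
  structure(list(records = records,
                 alignment = alignment,
                 truth = dplyr::select(truth, -"seq"),
                 templates = templates,
                 config = config),
            class = "gg_cohort")
}

#' Generate gene models for a synthetic cohort
#'
#' Gene structure mirrors the plant arrangement: type A and B genes get
#' four exons (three introns), type C genes five, with the fifth exon
#' encoding the cysteine-rich tail. Exon boundaries sit at shared
#' template-relative protein positions (after template residues 10, 30
#' and 50; the type C boundary after residue 60, the tail start), all at
#' phase 0, so projected boundaries land on identical alignment columns
#' across the cohort. Intron lengths and a per-gene genomic offset are
#' drawn from the cohort's seeded stream.
#'
#' @param cohort A `gg_cohort` from [make_cohort()].
#' @return A gene model tibble (`gene_id`, `exon`, `start`, `end`,
#'   `includes_stop`), CDS lengths `3 * (protein_length + 1)` (stop codon
#'   included).
#' @export
make_gene_models <- function(cohort) {
  stopifnot(inherits(cohort, "gg_cohort"))
  cfg <- cohort$config
  set.seed(cfg$seed + 104729L)  # independent, reproducible stream for gene structure
  truth <- cohort$truth
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    nl <- truth$nterm_len[i]
    prot_len <- nl + nchar(truth$central[i]) + truth$tail_len[i]
    cds <- 3L * (prot_len + 1L)
    tmpl_bounds <- c(10L, 30L, 50L)
    if (truth$true_type[i] == "C") tmpl_bounds <- c(tmpl_bounds, 60L)
    c_i <- 3L * (nl + tmpl_bounds)
    exon_len <- diff(c(0L, c_i, cds))
    introns <- sample(cfg$intron_len_range[1]:cfg$intron_len_range[2],
                      length(exon_len) - 1L, replace = TRUE)
    offset <- sample.int(1000L, 1)
    starts <- integer(length(exon_len)); ends <- integer(length(exon_len))
    pos <- offset
    for (e in seq_along(exon_len)) {
      starts[e] <- pos
      ends[e] <- pos + exon_len[e] - 1L
      pos <- ends[e] + 1L + if (e < length(exon_len)) introns[e] else 0L
    }
    rows[[i]] <- tibble(gene_id = truth$id[i], exon = seq_along(exon_len),
                        start = starts, end = ends, includes_stop = TRUE)
  }
  dplyr::bind_rows(rows)
}
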