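#' Per-gene exon/intron summary
#'
#' @param models Gene model tibble from [read_gene_models()] or
#'   [make_gene_models()] (columns `gene_id`, `exon`, `start`, `end`,
#'   optionally `includes_stop`).
#' @return A tibble with one row per gene: `gene_id`, `n_exons`,
#'   `n_introns`, `cds_len`, `protein_len`.
#' @export
gene_structure <- function(models) {
  inc <- if ("includes_stop" %in% names(models)) models$includes_stop else TRUE
  models$..stop <- inc
  out <- dplyr::summarise(
    dplyr::group_by(models, .data$gene_id),
    n_exons = dplyr::n(),
    n_introns = dplyr::n() - 1L,
    cds_len = sum(.data$end - .data$start + 1L),
    includes_stop = .data$..stop[1],
    .groups = "drop"
  )
  out$protein_len <- out$cds_len %/% 3L - ifelse(out$includes_stop, 1L, 0L)
  dplyr::select(out, "gene_id", "n_exons", "n_introns", "cds_len", "protein_len")
}

#' Project exon boundaries onto protein coordinates
#'
#' For each internal exon boundary (after exon i, i < n_exons) with
#' cumulative CDS length c, the boundary falls inside the protein residue
#' `ceil(c / 3)` with phase `c mod 3` (the number of nucleotides of the
#' split codon that lie 5' of the boundary; phase 0 means the boundary
#' coincides with a codon boundary). The residue-plus-phase pair makes the
#' projection exactly invertible, so the original exon lengths are
#' recoverable.
#'
#' @param models Gene model tibble (see [read_gene_models()]).
#' @return A tibble with one row per boundary: `gene_id`, `boundary`
#'   (ordinal), `cds_pos` (cumulative CDS nucleotides before the boundary),
#'   `residue_index` (1-based protein position containing the boundary),
#'   `phase` (0/1/2). Single-exon genes contribute no rows.
#' @examples
#' m <- tibble::tibble(gene_id = "g", exon = 1:4,
#'                     start = c(1, 200, 400, 600), end = c(120, 295, 495, 662))
#' project_boundaries(m)
#' @export
project_boundaries <- function(models) {
  models <- dplyr::arrange(models, .data$gene_id, .data$start)
  by_gene <- split(models, models$gene_id)
  purrr::map_dfr(by_gene, function(g) {
    len <- g$end - g$start + 1L
    if (length(len) < 2) return(tibble())
    c_i <- cumsum(len)[-length(len)]
    tibble(gene_id = g$gene_id[1],
           boundary = seq_along(c_i),
           cds_pos = as.integer(c_i),
           residue_index = as.integer(ceiling(c_i / 3)),
           phase = as.integer(c_i %% 3L))
  })
}

#' Map projected boundaries onto alignment columns and flag shared ones
#'
#' Each boundary's residue index is carried through the gap structure of
#' that gene's protein row in the alignment (the column holding the
#' residue's non-gap character). Boundaries landing in the same alignment
#' column across genes are the "shared" intron positions.
#'
#' @param projections Output of [project_boundaries()].
#' @param alignment Alignment tibble whose `id`s include every projected
#'   `gene_id`.
#' @return A tibble: `gene_id`, `boundary`, `residue_index`, `phase`,
#'   `column` (alignment column), `n_genes_at_column` (how many genes have
#'   a boundary in that column), `shared` (`n_genes_at_column > 1`).
#' @export
compare_boundaries <- function(projections, alignment) {
  alignment <- as_alignment(alignment)
  missing <- setdiff(unique(projections$gene_id), alignment$id)
  if (length(missing) > 0) {
    stop_gt("gene(s) absent from the alignment: %s", paste(missing, collapse = ", "))
  }
  res2col <- lapply(stats::setNames(alignment$aseq, alignment$id), function(a) {
    which(chars(a) != "-")
  })
  col <- vapply(seq_len(nrow(projections)), function(i) {
    map <- res2col[[projections$gene_id[i]]]
    ri <- projections$residue_index[i]
    if (ri > length(map)) {
      stop_gt("boundary residue %d of gene '%s' is beyond its %d-residue protein",
              ri, projections$gene_id[i], length(map))
    }
    map[ri]
  }, integer(1))
  out <- dplyr::mutate(projections, column = col)
  counts <- dplyr::summarise(dplyr::group_by(out, .data$column),
                             n_genes_at_column = dplyr::n_distinct(.data$gene_id),
                             .groups = "drop")
  out <- dplyr::left_join(out, counts, by = "column")
  out$shared <- out$n_genes_at_column > 1L
  dplyr::select(out, "gene_id", "boundary", "residue_index", "phase",
                "column", "n_genes_at_column", "shared")
}

#' Reconstruct exon lengths from a boundary projection
#'
#' Inverse of [project_boundaries()]: cumulative CDS positions are
#' `3 * (residue_index - 1) + phase` (with phase 0 meaning `3 * residue_index`),
#' and the final exon is recovered from the protein length.
#'
#' @param projection Rows of a single gene from [project_boundaries()].
#' @param protein_len Protein length in residues (without the stop).
#' @param includes_stop Whether the CDS carries a stop codon (default
#'   `TRUE`; adds one codon to the CDS total).
#' @return Integer vector of exon lengths in nucleotides.
#' @export
exon_lengths_from_projection <- function(projection, protein_len, includes_stop = TRUE) {
  c_i <- ifelse(projection$phase == 0L,
                3L * projection$residue_index,
                3L * (projection$residue_index - 1L) + projection$phase)
  total <- 3L * (protein_len + as.integer(includes_stop))
  as.integer(diff(c(0L, sort(c_i), total)))
}
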