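#' Read protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a tibble with one row per record.
#' Headers are interpreted as `id [species=...] [group=...]`, with both
#' bracketed attributes optional. Sequences are uppercased and a terminal
#' stop character (`*`) is stripped. Only the 20 standard amino-acid
#' letters plus `X` are accepted; `X` marks an unknown residue and is
#' treated as never matching in downstream identity computations.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A tibble with columns `id`, `species`, `group`, `seq`.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 [species=Arabidopsis thaliana] [group=eudicot]",
#'              "MAREVQKDPLLCGCSIL"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_gt("FASTA file not found: %s", path)
  if (!any(grepl("^>", readLines(path, warn = FALSE)))) {
    stop_gt("FASTA file '%s' contains no sequences", path)
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, forceDNAtolower = FALSE),
    error = function(e) stop_gt("could not parse FASTA file '%s': %s", path, conditionMessage(e))
  )
  headers <- vapply(recs, function(r) sub("^>", "", attr(r, "Annot")), character(1))
  parsed <- lapply(headers, parse_fasta_header)
  ids <- vapply(parsed, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop_gt("duplicate sequence id(s) in '%s': %s", path, paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- sub("\\*$", "", seqs)
  ok <- c(AA20, "X")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) stop_gt("record '%s' has an empty sequence", ids[i])
    bad <- which(!chars(seqs[i]) %in% ok)
    if (length(bad) > 0) {
      stop_gt("record '%s' has a non-amino-acid character '%s' at position %d",
              ids[i], substr(seqs[i], bad[1], bad[1]), bad[1])
    }
  }
  tibble(
    id = unname(ids),
    species = unname(vapply(parsed, `[[`, character(1), "species")),
    group = unname(vapply(parsed, `[[`, character(1), "group")),
    seq = unname(seqs)
  )
}

parse_fasta_header <- function(header) {
  species <- ""
  group <- ""
  m <- regmatches(header, regexec("\\[species=([^]]*)\\]", header))[[1]]
  if (length(m) == 2) species <- trimws(m[2])
  m <- regmatches(header, regexec("\\[group=([^]]*)\\]", header))[[1]]
  if (length(m) == 2) group <- trimws(m[2])
  id <- trimws(sub("\\[.*$", "", header))
  id <- strsplit(id, "[ \t]+")[[1]][1]
  if (is.na(id) || id == "") stop_gt("FASTA header with empty id: '>%s'", header)
  list(id = id, species = species, group = group)
}

#' Read an aligned FASTA file
#'
#' Reads a protein multiple sequence alignment in FASTA format. All rows
#' must have the same number of columns; `-` is the gap character.
#' De-gapping any row recovers that record's plain sequence.
#'
#' @param path Path to an aligned FASTA file.
#' @return A tibble with columns `id`, `species`, `group`, `aseq` and an
#'   `ncols` attribute giving the alignment width.
#' @export
read_alignment <- function(path) {
  tb <- read_alignment_chars(path)
  tb
}

read_alignment_chars <- function(path) {
  if (!file.exists(path)) stop_gt("alignment file not found: %s", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE, forceDNAtolower = FALSE)
  if (length(recs) == 0) stop_gt("alignment file '%s' contains no sequences", path)
  headers <- vapply(recs, function(r) sub("^>", "", attr(r, "Annot")), character(1))
  parsed <- lapply(headers, parse_fasta_header)
  ids <- vapply(parsed, `[[`, character(1), "id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop_gt("duplicate id(s) in alignment: %s", paste(unique(dup), collapse = ", "))
  aseqs <- toupper(vapply(recs, as.character, character(1)))
  aseqs <- sub("\\*$", "", aseqs)
  as_alignment(tibble(
    id = unname(ids),
    species = unname(vapply(parsed, `[[`, character(1), "species")),
    group = unname(vapply(parsed, `[[`, character(1), "group")),
    aseq = unname(aseqs)
  ))
}

#' Validate and tag an alignment tibble
#'
#' Checks that all rows of an alignment tibble (column `aseq`, gaps as `-`)
#' have equal width and records the width in the `ncols` attribute.
#'
#' @param data A data frame with columns `id` and `aseq`.
#' @return The validated tibble, with attribute `ncols`.
#' @export
as_alignment <- function(data) {
  if (!all(c("id", "aseq") %in% names(data))) {
    stop_gt("an alignment needs 'id' and 'aseq' columns")
  }
  w <- nchar(data$aseq)
  if (length(unique(w)) > 1) {
    off <- data$id[w != w[1]]
    stop_gt("ragged alignment: row(s) %s differ in length from row '%s'",
            paste(off, collapse = ", "), data$id[1])
  }
  out <- as_tibble(data)
  attr(out, "ncols") <- w[1]
  out
}

#' Alignment width (number of columns)
#' @param alignment An alignment tibble (see [read_alignment()]).
#' @return Integer column count.
#' @export
alignment_ncols <- function(alignment) {
  attr(alignment, "ncols") %||% unique(nchar(alignment$aseq))[1]
}

# Alignment rows as a character matrix (rows = sequences).
alignment_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$aseq, "", fixed = TRUE))
  rownames(m) <- alignment$id
  m
}

#' Write protein sequences to FASTA
#'
#' @param data Tibble with columns `id`, `seq` and optionally `species`,
#'   `group` (emitted as bracketed header attributes when non-empty).
#' @param path Output path.
#' @param seq_col Name of the sequence column (`"seq"` or `"aseq"`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, seq_col = "seq") {
  headers <- data$id
  if ("species" %in% names(data)) {
    has <- !is.na(data$species) & data$species != ""
    headers[has] <- paste0(headers[has], " [species=", data$species[has], "]")
  }
  if ("group" %in% names(data)) {
    has <- !is.na(data$group) & data$group != ""
    headers[has] <- paste0(headers[has], " [group=", data$group[has], "]")
  }
  lines <- as.vector(rbind(paste0(">", headers), data[[seq_col]]))
  tryCatch(writeLines(lines, path),
           error = function(e) stop_gt("cannot write FASTA to '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' Read gene models (ordered CDS exon spans)
#'
#' Reads coding-sequence exon coordinates, either from a TSV with columns
#' `gene_id`, `exon_start`, `exon_end`, or from a GFF3-like file (rows with
#' feature type `CDS`; the gene id is taken from the `Parent=` or `ID=`
#' attribute). Coordinates are 1-based inclusive on the coding strand.
#' Exons are sorted 5'->3'; overlaps and a total length not divisible by 3
#' are errors.
#'
#' @param path Path to the exon table.
#' @param includes_stop Does the final codon encode a stop? Default `TRUE`
#'   (a complete CDS); the protein length is the CDS length over three minus
#'   one when `TRUE`.
#' @return A tibble with columns `gene_id`, `exon` (ordinal), `start`,
#'   `end`, `includes_stop`.
#' @export
read_gene_models <- function(path, includes_stop = TRUE) {
  if (!file.exists(path)) stop_gt("gene model file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop_gt("gene model file '%s' is empty", path)
  nfield <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  if (nfield >= 8) {
    tb <- parse_gff_exons(lines)
  } else {
    df <- utils::read.delim(text = lines, sep = "\t", stringsAsFactors = FALSE)
    need <- c("gene_id", "exon_start", "exon_end")
    if (!all(need %in% names(df))) {
      stop_gt("gene model TSV needs columns %s", paste(need, collapse = ", "))
    }
    tb <- tibble(gene_id = as.character(df$gene_id),
                 start = as.integer(df$exon_start),
                 end = as.integer(df$exon_end))
  }
  validate_gene_models(tb, includes_stop)
}

parse_gff_exons <- function(lines) {
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 8 && x[3] == "CDS", logical(1))
  f <- f[keep]
  if (length(f) == 0) stop_gt("no CDS features found in GFF input")
  gene_id <- vapply(f, function(x) {
    attrs <- if (length(x) >= 9) x[9] else ""
    m <- regmatches(attrs, regexec("Parent=([^;]+)", attrs))[[1]]
    if (length(m) == 2) return(m[2])
    m <- regmatches(attrs, regexec("ID=([^;]+)", attrs))[[1]]
    if (length(m) == 2) return(m[2])
    stop_gt("CDS feature without Parent= or ID= attribute")
  }, character(1))
  tibble(gene_id = gene_id,
         start = as.integer(vapply(f, `[[`, character(1), 4)),
         end = as.integer(vapply(f, `[[`, character(1), 5)))
}

validate_gene_models <- function(tb, includes_stop = TRUE) {
  if (any(is.na(tb$start)) || any(is.na(tb$end))) stop_gt("non-numeric exon coordinates")
  if (any(tb$end < tb$start)) stop_gt("exon with end < start")
  tb <- dplyr::arrange(tb, .data$gene_id, .data$start)
  by_gene <- split(tb, tb$gene_id)
  for (g in by_gene) {
    if (nrow(g) > 1) {
      if (any(g$start[-1] <= g$end[-nrow(g)])) {
        stop_gt("overlapping or unordered exons in gene '%s'", g$gene_id[1])
      }
    }
    tot <- sum(g$end - g$start + 1)
    if (tot %% 3 != 0) {
      stop_gt("total CDS length of gene '%s' is %d nt, not divisible by 3", g$gene_id[1], tot)
    }
  }
  tb <- dplyr::mutate(dplyr::group_by(tb, .data$gene_id), exon = dplyr::row_number())
  tb <- dplyr::ungroup(tb)
  tb$includes_stop <- includes_stop
  dplyr::select(tb, "gene_id", "exon", "start", "end", "includes_stop")
}

#' Write a tree to Newick
#'
#' Writes an `ape` `phylo` tree with branch lengths and, when present,
#' internal-node support labels.
#'
#' @param tree A `phylo` object (or a `gg_phylo` result, whose point tree
#'   is written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "gg_phylo")) tree <- tree$tree
  if (!inherits(tree, "phylo")) stop_gt("write_newick() expects a 'phylo' object")
  ok <- tryCatch(ape::write.tree(tree, file = path), error = function(e) NULL)
  if (is.null(ok) && !file.exists(path)) stop_gt("cannot write Newick to '%s'", path)
  invisible(path)
}

#' Write a tabular report as TSV
#'
#' Writes a header row, UTF-8, `.` decimal separator; optional `#`-prefixed
#' comment lines (used by the command-line interface for provenance) go
#' before the header.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param comments Optional character vector of comment lines (written with
#'   a leading `# `).
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(table, path, comments = NULL) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop_gt("cannot open '%s' for writing", path))
  on.exit(close(con))
  if (length(comments) > 0) writeLines(paste0("# ", comments), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
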