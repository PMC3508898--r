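#' Majority-rule C-terminal consensus
#'
#' Right-anchors the sequences (position -1 is the last residue of every
#' sequence) and, at each of the last `k` positions, keeps the residue whose
#' frequency among contributing sequences strictly exceeds 50%; otherwise
#' the position is written as `x`. Sequences shorter than a position, gap
#' characters and `x` symbols do not contribute to that position's
#' denominator — the latter is what lets group-level consensi be joined
#' into a kingdom-level one.
#'
#' @param seqs Character vector of sequences, or a data frame with a `seq`
#'   column.
#' @param k Window length (number of C-terminal positions). Default 20.
#' @return A `gg_consensus` tibble with one row per position: `position`
#'   (negative index, -k .. -1), `residue` (winner or `"x"`), `support`
#'   (winning — or, for `x`, maximal — residue fraction), `n` (contributing
#'   sequences). The consensus string is in the `consensus` attribute and
#'   via [consensus_string()].
#' @examples
#' cterm_consensus(c("AKGSDFS", "KGSDFS"), k = 6)
#' @export
cterm_consensus <- function(seqs, k = 20) {
  seqs <- pull_seqs(seqs)
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) == 0) stop_gt("cterm_consensus() needs at least one sequence")
  if (k < 1) stop_gt("k must be >= 1")
  n <- nchar(seqs)
  rows <- lapply(seq_len(k), function(j) {
    # position -j: the j-th residue from the C-terminus
    contrib <- n >= j
    res <- substr(seqs[contrib], n[contrib] - j + 1L, n[contrib] - j + 1L)
    res <- res[!res %in% c("x", "-")]
    if (length(res) == 0) {
      return(tibble(position = -j, residue = "x", support = NA_real_, n = 0L))
    }
    tab <- table(res)
    frac <- as.numeric(tab) / length(res)
    top <- which.max(frac)
    win <- frac[top] > 0.5
    tibble(position = -j,
           residue = if (win) names(tab)[top] else "x",
           support = frac[top],
           n = length(res))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$position)
  cons <- collapse0(out$residue)
  attr(out, "consensus") <- cons
  attr(out, "k") <- k
  class(out) <- c("gg_consensus", class(out))
  out
}

#' Consensus string of a `gg_consensus` result
#' @param x A `gg_consensus` object.
#' @return The consensus as a single string (positions -k .. -1 left to
#'   right).
#' @export
consensus_string <- function(x) {
  attr(x, "consensus") %||% collapse0(x$residue)
}

#' Hierarchical (group-then-join) majority-rule consensus
#'
#' To keep an over-represented group from dominating, a consensus is first
#' computed per group and the group consensi are then joined by a second
#' majority-rule pass in which `x` positions do not contribute. Each group
#' therefore weighs equally regardless of its size.
#'
#' @param data A data frame with a sequence column and a grouping column.
#' @param k Window length. Default 20.
#' @param group Name of the grouping column. Default `"group"`.
#' @param seq Name of the sequence column. Default `"seq"`.
#' @return A `gg_consensus` tibble (see [cterm_consensus()]); the per-group
#'   consensus strings are kept in the `group_consensi` attribute.
#' @export
hierarchical_consensus <- function(data, k = 20, group = "group", seq = "seq") {
  if (!is.data.frame(data)) stop_gt("hierarchical_consensus() needs a data frame")
  if (!group %in% names(data)) stop_gt("no grouping column '%s'", group)
  g <- data[[group]]
  keep <- !is.na(data[[seq]])
  data <- data[keep, , drop = FALSE]
  g <- g[keep]
  if (nrow(data) == 0) stop_gt("all groups are empty")
  per_group <- vapply(split(data[[seq]], g), function(s) {
    consensus_string(cterm_consensus(s, k = k))
  }, character(1))
  out <- cterm_consensus(unname(per_group), k = k)
  attr(out, "group_consensi") <- per_group
  out
}

#' Position frequency matrix and information content
#'
#' The numeric data behind a sequence logo: per-position residue
#' frequencies over the 20 amino acids and the per-position information
#' content in bits, `log2(20) - H` with `H` the Shannon entropy of the
#' column. Gaps and `X` do not contribute to a column's denominator.
#'
#' @param seqs Character vector of sequences (aligned, equal length, for
#'   `right_anchored = FALSE`) or arbitrary-length sequences to be
#'   right-anchored; also accepts a data frame with a `seq` or `aseq`
#'   column.
#' @param right_anchored If `TRUE`, position `-1` is every sequence's last
#'   residue and positions are negative; if `FALSE` (default), sequences
#'   must be equal length and positions are alignment columns 1..ncols.
#' @param k For right-anchored input, how many C-terminal positions to
#'   report (default: the longest sequence).
#' @return A tibble with columns `position`, `residue`, `freq`, `n`,
#'   `info_bits` (one row per position x residue with nonzero count;
#'   `info_bits` is repeated within a position).
#' @export
frequency_matrix <- function(seqs, right_anchored = FALSE, k = NULL) {
  if (is.data.frame(seqs)) {
    col <- if ("aseq" %in% names(seqs)) "aseq" else "seq"
    seqs <- pull_seqs(seqs, seq_col = col)
  }
  if (length(seqs) == 0) stop_gt("frequency_matrix() needs at least one sequence")
  n <- nchar(seqs)
  if (right_anchored) {
    k <- k %||% max(n)
    positions <- -seq_len(k)
    get_col <- function(j) {
      contrib <- n >= -j
      substr(seqs[contrib], n[contrib] + j + 1L, n[contrib] + j + 1L)
    }
  } else {
    if (length(unique(n)) > 1) {
      stop_gt("sequences are not equal length; use right_anchored = TRUE or align them")
    }
    positions <- seq_len(n[1])
    get_col <- function(j) substr(seqs, j, j)
  }
  purrr::map_dfr(positions, function(j) {
    res <- get_col(j)
    res <- res[res %in% AA20]
    if (length(res) == 0) {
      return(tibble(position = j, residue = NA_character_, freq = NA_real_,
                    n = 0L, info_bits = NA_real_))
    }
    tab <- table(factor(res, levels = AA20))
    p <- as.numeric(tab) / length(res)
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    keep <- p > 0
    tibble(position = j, residue = AA20[keep], freq = p[keep],
           n = length(res), info_bits = log2(20) - h)
  })
}
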