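#' Find short tandem repeats in a sequence region
#'
#' Scans every start position and unit length for arrays of two or more
#' adjacent copies of a short unit, the pattern typical of recently
#' amplified stretches in cysteine-rich Ggamma tails. An array is grown
#' copy by copy while the next unit's identity to the running consensus
#' stays at or above `min_identity`; the consensus is the per-column
#' majority over the copies accepted so far (ties resolved to the first
#' copy's residue). Overlapping candidates are resolved greedily: larger
#' span (`n_copies * unit_len`) first, ties to the leftmost start, then to
#' the shorter unit; arrays nested in an accepted one are dropped.
#'
#' @param region A single sequence region (string).
#' @param unit_range Length-2 integer vector, inclusive range of unit
#'   lengths to consider. Default `c(5, 10)`.
#' @param min_identity Minimum per-copy identity to the running consensus.
#'   Default 0.7.
#' @return A tibble with one row per accepted array: `start` (1-based),
#'   `unit_len`, `n_copies`, `mean_identity` (mean identity of the copies
#'   to the final consensus), `unit_consensus`.
#' @examples
#' find_tandem_repeats(strrep("CKSPC", 3), unit_range = c(5, 10))
#' @export
find_tandem_repeats <- function(region, unit_range = c(5, 10), min_identity = 0.7) {
  stopifnot(length(region) == 1, is.character(region))
  u_min <- as.integer(unit_range[1]); u_max <- as.integer(unit_range[2])
  if (u_min < 1 || u_max < u_min) stop_gt("bad unit_range")
  n <- nchar(region)
  if (n < 2L * u_min) {
    return(tibble(start = integer(), unit_len = integer(), n_copies = integer(),
                  mean_identity = numeric(), unit_consensus = character()))
  }
  ch <- chars(region)
  cand <- list()
  for (u in u_min:u_max) {
    if (2L * u > n) break
    for (s in 1L:(n - 2L * u + 1L)) {
      arr <- grow_array(ch, s, u, min_identity)
      if (!is.null(arr)) cand[[length(cand) + 1L]] <- arr
    }
  }
  if (length(cand) == 0) {
    return(tibble(start = integer(), unit_len = integer(), n_copies = integer(),
                  mean_identity = numeric(), unit_consensus = character()))
  }
  df <- dplyr::bind_rows(cand)
  df$span <- df$n_copies * df$unit_len
  df <- df[order(-df$span, df$start, df$unit_len), , drop = FALSE]
  occ <- rep(FALSE, n)
  keep_rows <- integer(0)
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:(df$start[i] + df$span[i] - 1L)
    if (!any(occ[idx])) {
      occ[idx] <- TRUE
      keep_rows <- c(keep_rows, i)
    }
  }
  out <- df[keep_rows, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  tibble(start = out$start, unit_len = out$unit_len, n_copies = out$n_copies,
         mean_identity = out$mean_identity, unit_consensus = out$unit_consensus)
}

# Grow a tandem array at start s with unit length u; NULL if < 2 copies.
grow_array <- function(ch, s, u, min_identity) {
  n <- length(ch)
  copies <- list(ch[s:(s + u - 1L)])
  consensus <- copies[[1]]
  repeat {
    nxt_start <- s + length(copies) * u
    if (nxt_start + u - 1L > n) break
    nxt <- ch[nxt_start:(nxt_start + u - 1L)]
    if (sum(nxt == consensus) / u < min_identity) break
    copies[[length(copies) + 1L]] <- nxt
    consensus <- column_majority(copies)
  }
  if (length(copies) < 2L) return(NULL)
  ident <- vapply(copies, function(cp) sum(cp == consensus) / u, numeric(1))
  tibble(start = s, unit_len = u, n_copies = length(copies),
         mean_identity = mean(ident), unit_consensus = collapse0(consensus))
}

# Per-column majority over copies; ties go to the first copy's residue.
column_majority <- function(copies) {
  u <- length(copies[[1]])
  vapply(seq_len(u), function(j) {
    col <- vapply(copies, `[[`, character(1), j)
    tab <- table(col)
    best <- max(tab)
    winners <- names(tab)[tab == best]
    if (length(winners) == 1) winners else col[1]
  }, character(1))
}
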