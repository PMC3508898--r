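#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue classes used for C-terminal anchor composition.
AA_BASIC <- c("K", "R")
AA_AROMATIC <- c("W", "F")
AA_HYDROPHOBIC <- c("I", "L")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Collapse a character vector back into a string.
collapse0 <- function(x) paste(x, collapse = "")

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' @keywords internal
stop_gt <- function(msg, ...) rlang::abort(sprintf(msg, ...), class = "gammatype_error")

# Accept either a character vector of sequences or a data frame with a
# sequence column; returns the character vector (named by `id` if present).
pull_seqs <- function(x, seq_col = "seq") {
  if (is.data.frame(x)) {
    if (!seq_col %in% names(x)) {
      stop_gt("data frame input must contain a '%s' column", seq_col)
    }
    out <- x[[seq_col]]
    if ("id" %in% names(x)) names(out) <- x[["id"]]
    return(out)
  }
  if (!is.character(x)) stop_gt("expected a character vector or data frame of sequences")
  x
}
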