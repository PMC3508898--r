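#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.gg_consensus <- function(x, ...) {
  cat("C-terminal majority-rule consensus (k = ", attr(x, "k"), "):\n  ",
      consensus_string(x), "\n", sep = "")
  NextMethod()
}

#' Tidy a consensus result
#' @param x A `gg_consensus` object.
#' @param ... Unused.
#' @return The per-position tibble (`position`, `residue`, `support`, `n`).
#' @method tidy gg_consensus
#' @export
tidy.gg_consensus <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gg_consensus")
  attr(out, "consensus") <- NULL
  attr(out, "k") <- NULL
  out
}

#' One-row summary of a consensus result
#' @param x A `gg_consensus` object.
#' @param ... Unused.
#' @return A tibble: `k`, `consensus`, `mean_support`, `n_variable` (count
#'   of `x` positions).
#' @method glance gg_consensus
#' @export
glance.gg_consensus <- function(x, ...) {
  tibble(k = attr(x, "k"),
         consensus = consensus_string(x),
         mean_support = mean(x$support, na.rm = TRUE),
         n_variable = sum(x$residue == "x"))
}

#' Plot per-position consensus support
#' @param object A `gg_consensus` object.
#' @param ... Unused.
#' @return A ggplot: support by C-terminal position, labeled with the
#'   winning residue.
#' @method autoplot gg_consensus
#' @export
autoplot.gg_consensus <- function(object, ...) {
  df <- tidy.gg_consensus(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$support)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = "position from C-terminus", y = "winning residue fraction",
                  title = "Majority-rule C-terminal consensus") +
    ggplot2::theme_minimal()
}

#' @export
print.gg_phylo <- function(x, ...) {
  cat("Neighbor-joining tree with bootstrap bipartition support\n")
  cat("  taxa: ", length(x$tree$tip.label),
      "; replicates: ", x$n_replicates,
      "; seed: ", x$seed, "; model: ", x$model, "\n", sep = "")
  df <- x$support
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-12s n=%-3d support=%s\n", df$group[i], df$n_taxa[i],
                ifelse(is.na(df$support[i]), "undefined", format(df$support[i]))))
  }
  invisible(x)
}

#' Tidy bootstrap support
#' @param x A `gg_phylo` object.
#' @param ... Unused.
#' @return The support tibble (`group`, `support`, `n_taxa`).
#' @method tidy gg_phylo
#' @export
tidy.gg_phylo <- function(x, ...) x$support

#' One-row summary of a bootstrap analysis
#' @param x A `gg_phylo` object.
#' @param ... Unused.
#' @return A tibble: `n_taxa`, `n_groups`, `n_replicates`, `seed`, `model`,
#'   `min_support`.
#' @method glance gg_phylo
#' @export
glance.gg_phylo <- function(x, ...) {
  tibble(n_taxa = length(x$tree$tip.label),
         n_groups = nrow(x$support),
         n_replicates = x$n_replicates,
         seed = x$seed,
         model = x$model,
         min_support = suppressWarnings(min(x$support$support, na.rm = TRUE)))
}

#' Plot bootstrap support per group
#' @param object A `gg_phylo` object.
#' @param ... Unused.
#' @return A ggplot bar chart of group supports.
#' @method autoplot gg_phylo
#' @export
autoplot.gg_phylo <- function(object, ...) {
  df <- object$support[!is.na(object$support$support), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$support)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.95, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "bootstrap bipartition support",
                  title = sprintf("Monophyly support (%d replicates)", object$n_replicates)) +
    ggplot2::theme_minimal()
}

#' Plot the type composition of a classification
#' @param object A `gg_typecalls` tibble from [classify_gg()].
#' @param ... Unused.
#' @return A ggplot bar chart of label counts, filled by transferase call.
#' @method autoplot gg_typecalls
#' @export
autoplot.gg_typecalls <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, fill = .data$transferase)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "structural type", y = "sequences",
                  title = "Ggamma structural type calls") +
    ggplot2::theme_minimal()
}

#' One-row summary of a classification
#' @param x A `gg_typecalls` tibble.
#' @param ... Unused.
#' @return A tibble with one column per label count plus `n` and the
#'   thresholds used.
#' @method glance gg_typecalls
#' @export
glance.gg_typecalls <- function(x, ...) {
  p <- attr(x, "params_used")
  tibble(n = nrow(x),
         n_A = sum(x$label == "A"), n_B = sum(x$label == "B"),
         n_C = sum(x$label == "C"),
         n_unclassified = sum(x$label == "unclassified"),
         l_c = p$l_c, c_min = p$c_min, window = p$window)
}
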