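# Temp-file fixtures built in code; nothing binary, nothing stored.

write_tmp_fasta <- function(lines, ext = ".faa") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

write_tmp_models <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# A ~100-residue type A protein in the AGG2 mould: anchored central domain,
# short tail ending in the dual-lipidation CGCSIL terminus.
agg2_like <- function() {
  paste0(strrep("M", 2), strrep("KNS", 10), gg_template()$seq, "QTRAEG", "CGCSIL")
}

cli_path <- function() {
  p <- system.file("cli", "gammatype.R", package = "gammatype")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(args, wd = tempdir()) {
  withr::with_dir(wd, {
    out <- suppressWarnings(system2("Rscript", c(cli_path(), args),
                                    stdout = TRUE, stderr = TRUE))
    list(status = attr(out, "status") %||% 0L, output = out)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
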