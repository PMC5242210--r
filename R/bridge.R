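## Interface to the bundled RDKit helper (inst/python/chem_bridge.py).
## Every call is batched: one python process per table, TSV in / TSV out.

bridge_script <- function() {
  system.file("python", "chem_bridge.py", package = "asbscaffold", mustWork = TRUE)
}

python_binary <- function() {
  py <- getOption("asbscaffold.python", Sys.getenv("ASB_PYTHON", "python"))
  if (!nzchar(Sys.which(py))) {
    stop("python interpreter not found: ", py,
         " (set options(asbscaffold.python=) or ASB_PYTHON)", call. = FALSE)
  }
  py
}

write_bridge_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

## SMILES contain '#' (triple bonds) and quotes are meaningless here, so both
## comment and quote handling must be disabled on read.
read_bridge_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL, check.names = FALSE)
}

run_bridge <- function(mode, input, rules_path = NULL) {
  fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(fout), add = TRUE)
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    fin <- input
  } else {
    fin <- tempfile(fileext = ".tsv")
    on.exit(unlink(fin), add = TRUE)
    write_bridge_tsv(input, fin)
  }
  args <- c(bridge_script(), mode, "--in", fin, "--out", fout)
  if (!is.null(rules_path)) args <- c(args, "--rules", rules_path)
  status <- system2(python_binary(), shQuote(args),
                    stdout = FALSE, stderr = "")
  if (status != 0L) {
    stop("chem_bridge.py ", mode, " failed (exit ", status, ")", call. = FALSE)
  }
  read_bridge_tsv(fout)
}
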