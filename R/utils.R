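# Shared internal helpers: deterministic TSV I/O, logging, seed derivation.

#' @importFrom data.table fread fwrite as.data.table data.table setkeyv :=
NULL

# Deterministic TSV writers/readers used for every tabular artifact.
writeTsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "",
                     eol = "\n", scipen = 50)
  invisible(path)
}

readTsv <- function(path, sep = "\t", colClasses = NULL) {
  as.data.frame(data.table::fread(path, sep = sep, header = TRUE,
                                  na.strings = "", colClasses = colClasses,
                                  data.table = FALSE, showProgress = FALSE))
}

# Lightweight uniform logging: messages to console plus optional file.
gowiseLog <- function(..., logfile = NULL, phase = "gowise") {
  txt <- paste0("[", phase, "] ", paste0(..., collapse = ""))
  message(txt)
  if (!is.null(logfile))
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), txt, "\n",
        sep = "", file = logfile, append = TRUE)
  invisible(txt)
}

# Derive a 32-bit task seed from the master seed and a string key, so every
# (term) task owns an independent, worker-order-invariant RNG stream.
# All intermediates stay below 2^53 so double arithmetic is exact.
deriveSeed <- function(seed, key) {
  p <- 2147483647
  s <- as.numeric(seed) %% p
  s <- (s * 48271) %% p          # 48271 * 2^31 < 2^53: exact
  for (v in utf8ToInt(key)) s <- (s * 131 + v) %% p
  as.integer(s)
}

# Geometric sequence helper for penalty grids.
geomSeq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
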