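# internal helpers shared across modules

# field separator from file extension: .csv -> comma, anything else -> tab
sniff_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

read_delim_sniffed <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", na.strings = NULL,
                    fileEncoding = "UTF-8", ...)
}

write_delim_sniffed <- function(df, path) {
  utils::write.table(df, path, sep = sniff_sep(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# numbers rendered so that re-parsing reproduces the double exactly
# (15 significant digits round-trips all inputs with <= 6 fractional digits)
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, trim = TRUE, scientific = FALSE)
  }, character(1))
  out
}

geometric_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values", call. = FALSE)
  exp(mean(log(x)))
}

revcomp_chr <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTacgt-", "TGCAtgca-", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a local RNG stream; global .Random.seed is untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
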