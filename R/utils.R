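# Internal helpers: seeded substreams, TSV interchange, small validators.

# Deterministic 31-bit seed for a named substream of a global seed, so that
# adding a generator stream never perturbs the draws of another.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Write a tab-separated interchange file
#'
#' All pipeline stages exchange plain UTF-8 TSV with a mandatory header,
#' '.' as the decimal mark and the literal string NA for missing values.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a tab-separated interchange file
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA",
                                  header = TRUE, showProgress = FALSE))
}

stop_if_not_prob <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]")
  }
  invisible(x)
}
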