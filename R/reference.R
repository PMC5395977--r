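#' Synthetic mitochondrial reference sequence
#'
#' A fixed pseudo-random 16,569-base sequence standing in for the human
#' mitochondrial reference (rCRS length). It is SYNTHETIC: base identities
#' carry no biological meaning, but the sequence is frozen (internal seed,
#' independent of any user seed), so reference alleles at the p9 sites are
#' stable across sessions and the simulated reads always match it away from
#' planted mismatches.
#'
#' @param as_string return a single string instead of a character vector of
#'   single bases.
#' @return character vector of length 16569 (or a single string).
#' @export
mt_reference <- function(as_string = FALSE) {
  ref <- .mtp9_cache$reference
  if (is.null(ref)) {
    ref <- with_seed(101L, sample(c("A", "C", "G", "T"), 16569L, replace = TRUE))
    .mtp9_cache$reference <- ref
    .mtp9_cache$reference_string <- paste(ref, collapse = "")
  }
  if (as_string) .mtp9_cache$reference_string else ref
}

.mtp9_cache <- new.env(parent = emptyenv())

#' Name and length of the synthetic mitochondrial contig
#' @return list with `name` and `length`.
#' @export
mt_contig <- function() list(name = "chrM", length = 16569L)
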