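# Text SAM reading/writing for the mitochondrial contig.
#
# Alignments are carried internally as a data.frame with the first eleven
# mandatory SAM columns (qname, flag, rname, pos, mapq, cigar, rnext, pnext,
# tlen, seq, qual). Only single-contig, text SAM is supported: upstream
# alignment and NUMT-aware filtering are out of scope, and the simulator
# emits exactly this shape.

SAM_COLS <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "rnext", "pnext", "tlen", "seq", "qual")

#' Write alignments to a text SAM file
#'
#' @param aln alignment data.frame (see [read_sam()]).
#' @param path output path.
#' @param sort_reads sort by position then name for deterministic output.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, sort_reads = TRUE) {
  ctg <- mt_contig()
  if (sort_reads && nrow(aln)) aln <- aln[order(aln$pos, aln$qname), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", ctg$name, ctg$length))
  body <- if (nrow(aln)) {
    do.call(paste, c(unname(as.list(aln[, SAM_COLS])), sep = "\t"))
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a text SAM file
#'
#' Header lines are skipped; the first eleven mandatory fields of each
#' alignment line are returned. Malformed lines (fewer than 11 fields or a
#' non-numeric POS) are returned separately rather than raising.
#'
#' @param path SAM file path.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual` and attribute
#'   `n_malformed`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    out <- data.frame(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      rnext = character(), pnext = integer(), tlen = integer(),
                      seq = character(), qual = character(), stringsAsFactors = FALSE)
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  ok <- if (length(parts) >= 11L) {
    !is.na(parts[[1L]]) & !is.na(parts[[11L]]) &
      !is.na(suppressWarnings(as.integer(parts[[4L]])))
  } else rep(FALSE, length(lines))
  if (length(parts) < 11L) stop("not a SAM file (fewer than 11 fields): ", path)
  out <- data.frame(
    qname = parts[[1L]][ok],
    flag = as.integer(parts[[2L]][ok]),
    rname = parts[[3L]][ok],
    pos = as.integer(parts[[4L]][ok]),
    mapq = as.integer(parts[[5L]][ok]),
    cigar = parts[[6L]][ok],
    rnext = parts[[7L]][ok],
    pnext = as.integer(parts[[8L]][ok]),
    tlen = as.integer(parts[[9L]][ok]),
    seq = parts[[10L]][ok],
    qual = parts[[11L]][ok],
    stringsAsFactors = FALSE
  )
  attr(out, "n_malformed") <- sum(!ok)
  out
}

# --- CIGAR arithmetic -------------------------------------------------------

cigar_ops <- function(cigar) {
  if (cigar == "*") return(data.frame(len = integer(), op = character()))
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# Reference bases consumed by each CIGAR (vectorised; fast path for the
# ubiquitous single-block "<n>M").
cigar_ref_width <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  for (i in which(!simple)) {
    o <- cigar_ops(cigar[i])
    out[i] <- sum(o$len[o$op %in% c("M", "D", "N", "=", "X")])
  }
  out
}

# 1-based query offset of the read base aligned to reference offset
# `ref_off` (1 = leftmost aligned reference base), or NA when the position
# falls in a deletion/skip.
cigar_query_offset <- function(cigar, ref_off) {
  o <- cigar_ops(cigar)
  q <- 0L
  r <- 0L
  for (i in seq_len(nrow(o))) {
    op <- o$op[i]
    len <- o$len[i]
    if (op %in% c("M", "=", "X")) {
      if (ref_off <= r + len) return(q + (ref_off - r))
      q <- q + len
      r <- r + len
    } else if (op %in% c("I", "S")) {
      q <- q + len
    } else if (op %in% c("D", "N")) {
      if (ref_off <= r + len) return(NA_integer_)
      r <- r + len
    }
  }
  NA_integer_
}
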