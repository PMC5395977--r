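# Alignment ingest: read filtering, per-site allele counts, read termini.

FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPL <- 0x800L

#' Classify alignments as kept or rejected
#'
#' Implements the "properly paired and uniquely mapped" read filter: a read
#' is kept iff its proper-pair flag is set, it is not unmapped, secondary,
#' supplementary or duplicate-marked, and its mapping quality is at least
#' `min_mapq`. Unique mapping is operationalized as a MAPQ floor (STAR
#' emits 255 for unique alignments); the threshold is a parameter.
#'
#' @param aln alignment data.frame ([read_sam()] shape).
#' @param min_mapq minimum mapping quality (default 30).
#' @param require_proper_pair drop reads without the proper-pair flag.
#' @param drop_duplicates drop duplicate-marked reads (conservative default).
#' @return character vector, one per row: "keep" or a reason code among
#'   "unmapped", "secondary", "supplementary", "duplicate", "pairing",
#'   "mapq", "malformed".
#' @export
filter_read <- function(aln, min_mapq = 30L, require_proper_pair = TRUE,
                        drop_duplicates = TRUE) {
  n <- nrow(aln)
  reason <- rep("keep", n)
  flag <- aln$flag
  malformed <- is.na(flag) | is.na(aln$pos) | is.na(aln$mapq) |
    is.na(aln$cigar) | aln$cigar == "" | flag < 0L
  set_reason <- function(reason, bad, code) {
    ifelse(reason == "keep" & bad, code, reason)
  }
  reason <- set_reason(reason, malformed, "malformed")
  reason <- set_reason(reason, bitwAnd(flag, FLAG_UNMAPPED) > 0L, "unmapped")
  reason <- set_reason(reason, bitwAnd(flag, FLAG_SECONDARY) > 0L, "secondary")
  reason <- set_reason(reason, bitwAnd(flag, FLAG_SUPPL) > 0L, "supplementary")
  if (drop_duplicates) {
    reason <- set_reason(reason, bitwAnd(flag, FLAG_DUP) > 0L, "duplicate")
  }
  if (require_proper_pair) {
    reason <- set_reason(reason, bitwAnd(flag, FLAG_PROPER) == 0L, "pairing")
  }
  reason <- set_reason(reason, aln$mapq < min_mapq, "mapq")
  reason
}

#' Apply the read filter, returning kept reads and a rejection log
#'
#' @inheritParams filter_read
#' @return list with `kept` (alignment data.frame) and `rejected`
#'   (data.frame of reason counts).
#' @export
filter_reads <- function(aln, min_mapq = 30L, require_proper_pair = TRUE,
                         drop_duplicates = TRUE) {
  reason <- filter_read(aln, min_mapq, require_proper_pair, drop_duplicates)
  tab <- table(factor(reason[reason != "keep"],
                      levels = c("malformed", "unmapped", "secondary",
                                 "supplementary", "duplicate", "pairing", "mapq")))
  list(kept = aln[reason == "keep", , drop = FALSE],
       rejected = data.frame(reason = names(tab), n = as.integer(tab),
                             stringsAsFactors = FALSE))
}

#' Count alleles at p9 sites
#'
#' Pileup-style A/C/G/T counts at each annotated site among filtered reads,
#' keeping only bases with quality at least `min_base_quality` (default 13,
#' the pileup convention). Deletions and reference skips at the site are
#' excluded, so depth is the sum of the four base counts by definition.
#'
#' @param aln filtered alignment data.frame.
#' @param sites site table ([p9_sites()] shape).
#' @param sample_id label stamped on every output row.
#' @param min_base_quality minimum Phred base quality.
#' @return data.frame with columns `sample_id`, `site_id`, `count_A`,
#'   `count_C`, `count_G`, `count_T`, `depth`.
#' @export
count_alleles <- function(aln, sites, sample_id = "sample",
                          min_base_quality = 13L) {
  sites <- validate_sites(sites)
  n <- nrow(sites)
  out <- data.frame(sample_id = rep(sample_id, n), site_id = sites$site_id,
                    count_A = 0L, count_C = 0L, count_G = 0L, count_T = 0L,
                    depth = 0L, stringsAsFactors = FALSE)
  if (!nrow(aln)) return(out)
  width <- cigar_ref_width(aln$cigar)
  end <- aln$pos + width - 1L
  simple <- grepl("^[0-9]+M$", aln$cigar)
  for (i in seq_len(n)) {
    p <- sites$position[i]
    idx <- which(aln$pos <= p & end >= p)
    if (!length(idx)) next
    ref_off <- p - aln$pos[idx] + 1L
    qoff <- integer(length(idx))
    qoff[simple[idx]] <- ref_off[simple[idx]]
    for (j in which(!simple[idx])) {
      qoff[j] <- cigar_query_offset(aln$cigar[idx[j]], ref_off[j])
    }
    ok <- !is.na(qoff)
    idx <- idx[ok]
    qoff <- qoff[ok]
    if (!length(idx)) next
    base <- substr(aln$seq[idx], qoff, qoff)
    bq <- utf8ToInt(paste(substr(aln$qual[idx], qoff, qoff), collapse = "")) - 33L
    keep <- bq >= min_base_quality & base %in% c("A", "C", "G", "T")
    cnt <- table(factor(base[keep], levels = c("A", "C", "G", "T")))
    out$count_A[i] <- cnt[["A"]]
    out$count_C[i] <- cnt[["C"]]
    out$count_G[i] <- cnt[["G"]]
    out$count_T[i] <- cnt[["T"]]
    out$depth[i] <- sum(cnt)
  }
  out
}

#' Count read termini and coverage at positions
#'
#' For each requested position, counts filtered reads whose first aligned
#' base is that position (`n_start`), whose last aligned base is that
#' position (`n_end`), and all reads covering it (`n_cover`). Soft-clipped
#' bases do not count as aligned, so POS/CIGAR arithmetic defines the
#' termini.
#'
#' @param aln filtered alignment data.frame.
#' @param positions integer vector of 1-based positions.
#' @param sample_id label stamped on every output row.
#' @return data.frame with columns `sample_id`, `position`, `n_start`,
#'   `n_end`, `n_cover`.
#' @export
count_termini <- function(aln, positions, sample_id = "sample") {
  positions <- as.integer(positions)
  if (any(is.na(positions)) || any(positions < 1L)) stop("invalid positions")
  if (any(positions > mt_contig()$length)) {
    stop("position beyond contig length: ",
         paste(positions[positions > mt_contig()$length], collapse = ", "))
  }
  if (nrow(aln)) {
    width <- cigar_ref_width(aln$cigar)
    starts <- aln$pos
    ends <- aln$pos + width - 1L
    n_start <- vapply(positions, function(p) sum(starts == p), integer(1))
    n_end <- vapply(positions, function(p) sum(ends == p), integer(1))
    n_cover <- vapply(positions, function(p) sum(starts <= p & ends >= p), integer(1))
  } else {
    n_start <- n_end <- n_cover <- integer(length(positions))
  }
  data.frame(sample_id = sample_id, position = positions,
             n_start = n_start, n_end = n_end, n_cover = n_cover,
             stringsAsFactors = FALSE)
}

#' Positions needing terminus records for the cleavage statistics
#'
#' For each site: the cleavage boundary position, the control position 9
#' bases further upstream, the base abutting each on the tRNA side, and
#' the p9 position itself.
#'
#' @param sites site table.
#' @return sorted integer vector of positions.
#' @export
terminus_positions <- function(sites) {
  pos <- unlist(lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    c1 <- cleavage_position(s)
    c2 <- cleavage_position(s, control = TRUE)
    adj <- if (s$strand == "+") c(c1 + 1L, c2 + 1L) else c(c1 - 1L, c2 - 1L)
    c(s$position, c1, c2, adj)
  }))
  sort(unique(as.integer(pos)))
}
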