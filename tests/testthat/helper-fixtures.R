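# Constructors for small alignment fixtures and independent oracles used
# across test files. Fixtures are built in code; nothing binary ships.

# One alignment row per element of `pos`; seq defaults to the reference
# substring so constructed reads are all-reference unless overridden.
make_aln <- function(pos, len = 20L, seq = NULL, qual = NULL, flag = 99L,
                     mapq = 60L, cigar = NULL, qname = NULL) {
  n <- length(pos)
  refstr <- mt_reference(as_string = TRUE)
  if (is.null(cigar)) cigar <- rep(paste0(len, "M"), n)
  if (is.null(seq)) seq <- substr(rep(refstr, n), pos, pos + len - 1L)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
  data.frame(qname = qname, flag = rep_len(flag, n), rname = "chrM",
             pos = as.integer(pos), mapq = rep_len(mapq, n), cigar = cigar,
             rnext = "=", pnext = as.integer(pos), tlen = 0L,
             seq = seq, qual = qual, stringsAsFactors = FALSE)
}

# Independent allele-count oracle: expand each read's aligned (ref, query)
# pairs base by base from the CIGAR, then tally bases at the site.
naive_count_oracle <- function(aln, site_pos, min_baseq = 13L) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in seq_len(nrow(aln))) {
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", aln$cigar[i])[[1]]
    toks <- regmatches(aln$cigar[i], gregexpr("[0-9]+[MIDNSHP=X]",
                                              aln$cigar[i]))[[1]]
    r <- aln$pos[i]
    q <- 1L
    for (tk in toks) {
      len <- as.integer(sub("[A-Z=]$", "", tk))
      op <- sub("^[0-9]+", "", tk)
      if (op %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          if (r == site_pos) {
            b <- substr(aln$seq[i], q, q)
            bq <- utf8ToInt(substr(aln$qual[i], q, q)) - 33L
            if (bq >= min_baseq && b %in% names(counts)) {
              counts[b] <- counts[b] + 1L
            }
          }
          r <- r + 1L
          q <- q + 1L
        }
      } else if (op %in% c("I", "S")) {
        q <- q + len
      } else if (op %in% c("D", "N")) {
        r <- r + len
      }
    }
  }
  counts
}

# Brute-force Ward clustering: greedy minimum increase in within-cluster
# SS, heights on the ward.D2 scale sqrt(2 * delta_SS); returns the full
# cophenetic matrix.
brute_ward_cophenetic <- function(m) {
  n <- nrow(m)
  cl <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  while (length(cl) > 1L) {
    best <- NULL
    bc <- Inf
    for (i in seq_len(length(cl) - 1L)) {
      for (j in seq(i + 1L, length(cl))) {
        a <- colMeans(m[cl[[i]], , drop = FALSE])
        b <- colMeans(m[cl[[j]], , drop = FALSE])
        na <- length(cl[[i]])
        nb <- length(cl[[j]])
        cost <- na * nb / (na + nb) * sum((a - b)^2)
        if (cost < bc) {
          bc <- cost
          best <- c(i, j)
        }
      }
    }
    h <- sqrt(2 * bc)
    for (u in cl[[best[1]]]) for (v in cl[[best[2]]]) {
      coph[u, v] <- coph[v, u] <- h
    }
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  coph
}

# Tiny two-cancer pairing manifest.
tiny_manifest <- function(n_per_cancer = 3L, cancers = c("CA", "CB")) {
  n <- n_per_cancer * length(cancers)
  pid <- sprintf("P%02d", seq_len(n))
  data.frame(patient_id = pid,
             cancer_type = rep(cancers, each = n_per_cancer),
             normal_sample_id = paste0(pid, "_N"),
             tumor_sample_id = paste0(pid, "_T"),
             stringsAsFactors = FALSE)
}

# Allele-count row builder.
acr <- function(sample_id, site_id, A = 0L, C = 0L, G = 0L, T = 0L) {
  data.frame(sample_id = sample_id, site_id = site_id, count_A = A,
             count_C = C, count_G = G, count_T = T, depth = A + C + G + T,
             stringsAsFactors = FALSE)
}
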