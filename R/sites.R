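#' Annotated mt-tRNA p9 sites
#'
#' The default annotation of the eleven mitochondrial tRNA ninth-position
#' (p9) sites subject to m1A/m1G methylation, at genomic positions 585,
#' 1610, 4271, 5520, 7526, 8303, 9999, 10413, 12174, 12246 and 14734.
#' All but the glutamate tRNA (site 14734) lie on the heavy (+) strand.
#' tRNA spans are nominal 69-base windows placing the p9 site at the ninth
#' base in tRNA orientation; the reference allele is taken from
#' [mt_reference()] so the invariant `ref_allele == reference[position]`
#' holds by construction. The table is user-overridable everywhere it is
#' consumed: any data.frame with the same columns is accepted.
#'
#' Published site lists disagree on one position (12174 in the methods-level
#' list versus 12146 in downstream result tables); this annotation follows
#' the methods-level list and callers can swap the row if they prefer.
#'
#' @return data.frame with columns `site_id`, `position`, `trna_name`,
#'   `strand` ("+" heavy / "-" light), `ref_allele`, `trna_start`,
#'   `trna_end`.
#' @export
p9_sites <- function() {
  pos <- c(585L, 1610L, 4271L, 5520L, 7526L, 8303L,
           9999L, 10413L, 12174L, 12246L, 14734L)
  trna <- c("TRNF", "TRNV", "TRNI", "TRNW", "TRND", "TRNK",
            "TRNG", "TRNR", "TRNH", "TRNS2", "TRNE")
  strand <- c(rep("+", 10L), "-")
  len <- 69L
  start <- ifelse(strand == "+", pos - 8L, pos + 8L - (len - 1L))
  end <- start + len - 1L
  ref <- mt_reference()[pos]
  data.frame(site_id = paste0("p9_", pos), position = pos, trna_name = trna,
             strand = strand, ref_allele = ref,
             trna_start = as.integer(start), trna_end = as.integer(end),
             stringsAsFactors = FALSE)
}

# Validate a user-supplied site table; returns it with site_id as character.
validate_sites <- function(sites) {
  need <- c("site_id", "position", "strand", "ref_allele")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("site table lacks columns: ", paste(miss, collapse = ", "))
  if (any(sites$position < 1L)) stop("site positions must be >= 1")
  if (any(sites$position > mt_contig()$length)) {
    bad <- sites$site_id[sites$position > mt_contig()$length]
    stop("site beyond contig length: ", paste(bad, collapse = ", "))
  }
  if (!all(sites$ref_allele %in% c("A", "C", "G", "T"))) {
    stop("ref_allele must be one of A/C/G/T")
  }
  if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  sites$site_id <- as.character(sites$site_id)
  sites
}

# Genomic coordinate of the 5' cleavage boundary position c for a site:
# 9 bases upstream of the p9 site in tRNA orientation, optionally shifted
# a further 9 bases upstream (the control position).
cleavage_position <- function(site, control = FALSE) {
  off <- if (control) 18L else 9L
  if (site$strand == "+") site$position - off else site$position + off
}
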