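#' Resolve the exon/intron anatomy of circRNA events
#'
#' Matches each event's back-splicing junction (BSJ) to an annotated
#' transcript of its host gene whose exon boundaries coincide with the BSJ
#' coordinates, then records, in transcript (strand-aware) orientation:
#' A1/A2, the upstream/downstream BSJ exons (equal for single-exon
#' circRNAs); C1/C2, the adjacent exons outside the circle; and I1/I2, the
#' flanking introns.  For a first-exon circRNA C1/I1 are absent (flagged),
#' likewise C2/I2 at the transcript end.  Events with no boundary-matching
#' transcript are flagged unresolved and excluded from cis feature
#' extraction.
#'
#' @param events a \code{\link{CircEventSet}}.
#' @param exons exon \code{GRanges} from \code{\link{readExonsGtf}} (metadata
#'   \code{gene_id}, \code{transcript_id}, \code{exon_rank}).
#' @return the \code{CircEventSet} with anatomy metadata columns
#'   (\code{a1_start} ... \code{i2_end}, \code{transcript_id},
#'   \code{resolved}, \code{c1_missing}, \code{c2_missing}) added.
#' @export
resolveEventAnatomy <- function(events, exons) {
  gr <- eventRanges(events)
  n <- length(gr)
  na <- rep(NA_integer_, n)
  anat <- DataFrame(transcript_id = rep(NA_character_, n),
                    resolved = rep(FALSE, n),
                    c1_missing = rep(TRUE, n), c2_missing = rep(TRUE, n),
                    a1_start = na, a1_end = na, a2_start = na, a2_end = na,
                    c1_start = na, c1_end = na, c2_start = na, c2_end = na,
                    i1_start = na, i1_end = na, i2_start = na, i2_end = na)
  ex_by_tx <- split(seq_along(exons), exons$transcript_id)

  for (i in seq_len(n)) {
    bsj_s <- start(gr)[i]; bsj_e <- end(gr)[i]
    str_i <- as.character(strand(gr))[i]
    cand <- which(exons$gene_id == gr$host_gene[i] &
                    as.character(seqnames(exons)) ==
                      as.character(seqnames(gr))[i])
    if (!length(cand)) next
    txs <- sort(unique(exons$transcript_id[cand]))
    for (tx in txs) {
      idx <- ex_by_tx[[tx]]
      idx <- idx[order(exons$exon_rank[idx])]
      es <- start(exons)[idx]; ee <- end(exons)[idx]
      left <- which(es == bsj_s)   # exon starting at the genomic-left BSJ
      right <- which(ee == bsj_e)  # exon ending at the genomic-right BSJ
      if (length(left) != 1L || length(right) != 1L) next
      # transcript-oriented upstream (A1) / downstream (A2) BSJ exons
      if (str_i == "+") { ia1 <- left; ia2 <- right } else { ia1 <- right; ia2 <- left }
      if (exons$exon_rank[idx[ia1]] > exons$exon_rank[idx[ia2]]) next
      anat$transcript_id[i] <- tx
      anat$resolved[i] <- TRUE
      anat$a1_start[i] <- es[ia1]; anat$a1_end[i] <- ee[ia1]
      anat$a2_start[i] <- es[ia2]; anat$a2_end[i] <- ee[ia2]
      if (ia1 > 1L) {               # C1: exon preceding A1 in transcript order
        anat$c1_missing[i] <- FALSE
        anat$c1_start[i] <- es[ia1 - 1L]; anat$c1_end[i] <- ee[ia1 - 1L]
        if (str_i == "+") {         # I1 between C1 and A1
          anat$i1_start[i] <- ee[ia1 - 1L] + 1L
          anat$i1_end[i] <- es[ia1] - 1L
        } else {
          anat$i1_start[i] <- ee[ia1] + 1L
          anat$i1_end[i] <- es[ia1 - 1L] - 1L
        }
      }
      if (ia2 < length(idx)) {      # C2: exon following A2
        anat$c2_missing[i] <- FALSE
        anat$c2_start[i] <- es[ia2 + 1L]; anat$c2_end[i] <- ee[ia2 + 1L]
        if (str_i == "+") {
          anat$i2_start[i] <- ee[ia2] + 1L
          anat$i2_end[i] <- es[ia2 + 1L] - 1L
        } else {
          anat$i2_start[i] <- ee[ia2 + 1L] + 1L
          anat$i2_end[i] <- es[ia2] - 1L
        }
      }
      break
    }
  }
  if (any(!anat$resolved))
    message(sum(!anat$resolved), " event(s) had no boundary-matching ",
            "transcript and were flagged unresolved")
  mcols(gr) <- cbind(mcols(gr)[, c("event_id", "host_gene", "circ_type")],
                     anat)
  new("CircEventSet", ranges = gr)
}

# interval of an anatomy region for event i, or NULL when absent
.anatomyInterval <- function(gr, i, region) {
  s <- mcols(gr)[[paste0(tolower(region), "_start")]][i]
  e <- mcols(gr)[[paste0(tolower(region), "_end")]][i]
  if (is.na(s) || is.na(e) || s > e) return(NULL)
  c(start = s, end = e)
}

#' Sense-strand sequence of an anatomy region
#'
#' @param events a resolved \code{CircEventSet}.
#' @param i event index.
#' @param region one of \code{"A1","A2","C1","C2","I1","I2"}.
#' @param genome a \code{DNAStringSet}.
#' @return a \code{DNAString}, or \code{NULL} when the region is absent.
#' @export
regionSeq <- function(events, i, region, genome) {
  gr <- eventRanges(events)
  iv <- .anatomyInterval(gr, i, region)
  if (is.null(iv)) return(NULL)
  getRegionSeq(genome, as.character(seqnames(gr))[i], iv["start"], iv["end"],
               as.character(strand(gr))[i])
}

#' Spliced circular sequence of an event
#'
#' Concatenation of the circularised exons in transcript order, on the host
#' gene's sense strand.  Exons are taken from the matched transcript between
#' the BSJ boundaries.
#'
#' @param events resolved \code{CircEventSet}; \code{i} event index.
#' @param exons exon annotation used for resolution.
#' @param genome \code{DNAStringSet}.
#' @param i event index.
#' @return a \code{DNAString}.
#' @export
circularSeq <- function(events, i, exons, genome) {
  gr <- eventRanges(events)
  if (!isTRUE(gr$resolved[i])) stop("event anatomy not resolved")
  tx <- gr$transcript_id[i]
  idx <- which(exons$transcript_id == tx)
  idx <- idx[order(exons$exon_rank[idx])]
  keep <- start(exons)[idx] >= start(gr)[i] & end(exons)[idx] <= end(gr)[i]
  idx <- idx[keep]
  chrom <- as.character(seqnames(gr))[i]
  str_i <- as.character(strand(gr))[i]
  parts <- lapply(idx, function(j)
    getRegionSeq(genome, chrom, start(exons)[j], end(exons)[j], str_i))
  do.call(Biostrings::xscat, parts)
}
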