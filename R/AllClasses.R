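#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Set of circRNA back-splicing events
#'
#' Wraps a \link[GenomicRanges]{GRanges} whose ranges span the back-splicing
#' junction (BSJ) of each event.  Mandatory metadata columns are
#' \code{event_id}, \code{host_gene} and \code{circ_type}
#' (\code{"exonic"}, \code{"intronic"} or \code{"intergenic"}).  After
#' \code{\link{resolveEventAnatomy}} the anatomy columns
#' \code{a1_start .. i2_end} describe the two BSJ exons (A1 upstream, A2
#' downstream in transcript orientation), the adjacent exons (C1/C2) and the
#' flanking introns (I1/I2); absent intervals are \code{NA} with companion
#' flags.
#'
#' @slot ranges \code{GRanges} of BSJ spans with the metadata described above.
#' @export
setClass("CircEventSet", representation(ranges = "GRanges"))

setValidity("CircEventSet", function(object) {
  gr <- object@ranges
  msg <- character()
  need <- c("event_id", "host_gene", "circ_type")
  miss <- setdiff(need, colnames(mcols(gr)))
  if (length(miss))
    msg <- c(msg, paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(gr$event_id))
      msg <- c(msg, "duplicated event_id")
    bad <- !gr$circ_type %in% c("exonic", "intronic", "intergenic")
    if (any(bad))
      msg <- c(msg, "circ_type must be exonic/intronic/intergenic")
    if (any(as.character(strand(gr)) == "*"))
      msg <- c(msg, "strand must be + or -")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CircEventSet
#'
#' @param event_id character vector of unique event identifiers.
#' @param chrom,start,end BSJ span per event, 1-based closed coordinates
#'   (start of the first circularised exon to end of the last).
#' @param strand \code{"+"} or \code{"-"} (host gene strand).
#' @param host_gene,circ_type per-event annotations; \code{circ_type} one of
#'   \code{"exonic"}, \code{"intronic"}, \code{"intergenic"}.
#' @return A \code{CircEventSet}.
#' @export
CircEventSet <- function(event_id, chrom, start, end, strand,
                         host_gene = NA_character_,
                         circ_type = "exonic") {
  stopifnot(all(start <= end))
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$event_id <- as.character(event_id)
  mcols(gr)$host_gene <- rep_len(as.character(host_gene), length(gr))
  mcols(gr)$circ_type <- rep_len(as.character(circ_type), length(gr))
  new("CircEventSet", ranges = gr)
}

#' @describeIn CircEventSet-class number of events
#' @param x,object a \code{CircEventSet}
#' @export
setMethod("length", "CircEventSet", function(x) length(x@ranges))

#' @describeIn CircEventSet-class subset events
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "CircEventSet", function(x, i, j, ..., drop = TRUE) {
  new("CircEventSet", ranges = x@ranges[i])
})

setMethod("show", "CircEventSet", function(object) {
  gr <- object@ranges
  cat("CircEventSet with", length(gr), "events on",
      length(unique(as.character(seqnames(gr)))), "sequence(s)\n")
  if ("resolved" %in% colnames(mcols(gr)))
    cat("  anatomy resolved for", sum(gr$resolved), "event(s)\n")
})

#' @rdname CircEventSet-class
#' @export
eventIds <- function(x) x@ranges$event_id

#' @rdname CircEventSet-class
#' @export
eventRanges <- function(x) x@ranges

#' Junction-count container
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} with integer assays
#' \code{bsj} (back-splicing junction reads) and \code{fsj} (forward/linear
#' splicing junction reads), rows = events, columns = samples.  Cells where an
#' event was not quantified in a sample are \code{NA}.
#'
#' @param bsj,fsj integer matrices of identical dimension (events x samples).
#' @param event_id,sample_id optional dimnames overriding those of \code{bsj}.
#' @return A \code{SummarizedExperiment}.
#' @export
JunctionCountSet <- function(bsj, fsj, event_id = rownames(bsj),
                             sample_id = colnames(bsj)) {
  bsj <- as.matrix(bsj); fsj <- as.matrix(fsj)
  if (!identical(dim(bsj), dim(fsj)))
    stop("bsj and fsj must have identical dimensions")
  if (any(bsj < 0, na.rm = TRUE) || any(fsj < 0, na.rm = TRUE))
    stop("junction counts must be non-negative")
  dimnames(bsj) <- dimnames(fsj) <- list(event_id, sample_id)
  SummarizedExperiment(assays = list(bsj = bsj, fsj = fsj))
}

#' Junction ratio from BSJ/FSJ counts
#'
#' The fraction of splicing output at the BSJ boundaries attributed to
#' back-splicing: \code{c*BSJ / (c*BSJ + FSJ)}.  The default weight
#' \code{c = 2} counts each BSJ read as evidence for both boundaries, the
#' convention of BSJ-aware circRNA quantifiers; \code{c = 1} gives the plain
#' read proportion.
#'
#' @param bsj,fsj counts (vectors, matrices, or a \code{JunctionCountSet} as
#'   first argument with \code{fsj} missing).
#' @param c ratio weight on BSJ reads (1 or 2; default 2).
#' @return ratios in \code{[0,1]}; \code{NA} where \code{c*bsj + fsj == 0}.
#' @export
junctionRatio <- function(bsj, fsj, c = 2) {
  if (is(bsj, "SummarizedExperiment")) {
    fsj <- assay(bsj, "fsj"); bsj <- assay(bsj, "bsj")
  }
  den <- c * bsj + fsj
  out <- (c * bsj) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Per-base score track
#'
#' Holds a real-valued per-base signal (conservation, nucleosome occupancy,
#' predicted pairing, ...) as scored intervals.  Queries outside covered
#' regions return \code{fill} and are flagged.
#'
#' @slot intervals \code{GRanges} with a numeric \code{score} column.
#' @slot fill value returned for uncovered bases.
#' @export
setClass("ScoreTrack",
         representation(intervals = "GRanges", fill = "numeric"))

setValidity("ScoreTrack", function(object) {
  if (!"score" %in% colnames(mcols(object@intervals)))
    return("intervals must carry a 'score' metadata column")
  if (length(object@fill) != 1L) return("fill must be a single value")
  TRUE
})

#' @rdname ScoreTrack-class
#' @param intervals \code{GRanges} with a \code{score} column.
#' @param fill value for uncovered bases (default 0).
#' @export
ScoreTrack <- function(intervals, fill = 0) {
  new("ScoreTrack", intervals = intervals, fill = fill)
}

setMethod("show", "ScoreTrack", function(object) {
  cat("ScoreTrack:", length(object@intervals), "scored interval(s), fill =",
      object@fill, "\n")
})

#' Registry of RBP motifs and PSSMs
#'
#' Count features use IUPAC motif strings; score features use log2-odds
#' position-specific scoring matrices over A, C, G, T (U is read as T).
#'
#' @slot motifs named character vector of IUPAC motifs.
#' @slot pssms named list of 4 x w numeric matrices (rows A, C, G, T) of
#'   log2-odds scores.
#' @export
setClass("MotifRegistry",
         representation(motifs = "character", pssms = "list"))

setValidity("MotifRegistry", function(object) {
  msg <- character()
  if (length(object@motifs) && is.null(names(object@motifs)))
    msg <- c(msg, "motifs must be named")
  for (nm in names(object@pssms)) {
    m <- object@pssms[[nm]]
    if (!is.matrix(m) || nrow(m) != 4L || !all(is.finite(m)))
      msg <- c(msg, paste0("pssm '", nm, "' must be a finite 4 x w matrix"))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname MotifRegistry-class
#' @param motifs named character vector of IUPAC motif strings.
#' @param pssms named list of 4 x w log2-odds matrices (rows A,C,G,T).
#' @export
MotifRegistry <- function(motifs = character(), pssms = list()) {
  if (length(motifs)) {
    motifs <- toupper(chartr("U", "T", motifs))
    if (is.null(names(motifs))) names(motifs) <- motifs
  }
  new("MotifRegistry", motifs = motifs, pssms = pssms)
}

setMethod("show", "MotifRegistry", function(object) {
  cat("MotifRegistry:", length(object@motifs), "motif(s),",
      length(object@pssms), "PSSM(s)\n")
})

#' Max-abs feature normalizer
#'
#' Stores, per feature, the maximum absolute value seen in a training table.
#' \code{\link{applyNormalizer}} divides by the stored maximum and (for data
#' unseen at fit time) clips results above 1 back to 1.  Features that were
#' constant zero in training are flagged and map to 0.
#'
#' @slot max_abs named numeric vector of training maxima (0 kept for
#'   constant features, see \code{constant}).
#' @slot constant named logical: feature had max-abs 0 in training.
#' @export
setClass("MaxAbsNormalizer",
         representation(max_abs = "numeric", constant = "logical"))

setValidity("MaxAbsNormalizer", function(object) {
  if (is.null(names(object@max_abs))) return("max_abs must be named")
  if (!identical(names(object@max_abs), names(object@constant)))
    return("max_abs and constant must share names")
  if (any(object@max_abs < 0)) return("max_abs must be non-negative")
  TRUE
})

setMethod("show", "MaxAbsNormalizer", function(object) {
  cat("MaxAbsNormalizer over", length(object@max_abs), "features (",
      sum(object@constant), "constant )\n")
})

#' Dense-block neural network model
#'
#' Four dense blocks (linear -> batch normalization -> ReLU -> dropout) and a
#' sigmoid (binary head) or softmax (three-class head) output layer.  Dropout
#' is active only during training; prediction is deterministic.
#'
#' @slot config list of architecture / training settings
#'   (see \code{\link{modelConfig}}).
#' @slot params list of layer parameter matrices (weights, biases, batch-norm
#'   scale/shift and running statistics).
#' @slot feature_names character, input registry order the model expects.
#' @slot history data.frame with one row per epoch (loss, held-out AUROC).
#' @export
setClass("DenseCircModel",
         representation(config = "list", params = "list",
                        feature_names = "character", history = "data.frame"))

setMethod("show", "DenseCircModel", function(object) {
  cfg <- object@config
  cat("DenseCircModel (", cfg$head, " head)\n", sep = "")
  cat("  input ", length(object@feature_names), " features -> blocks ",
      paste(cfg$widths, collapse = "/"), "\n", sep = "")
  if (nrow(object@history)) {
    best <- which.max(object@history$test_auroc)
    cat("  trained ", nrow(object@history), " epoch(s); best held-out AUROC ",
        sprintf("%.4f", object@history$test_auroc[best]),
        " at epoch ", best, "\n", sep = "")
  }
})

#' @rdname DenseCircModel-class
#' @param object a \code{DenseCircModel}
#' @export
modelHistory <- function(object) object@history

#' @rdname DenseCircModel-class
#' @export
modelFeatureNames <- function(object) object@feature_names
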