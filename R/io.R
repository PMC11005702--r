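#' @importFrom utils read.delim write.table
#' @importFrom Biostrings readDNAStringSet DNAString DNAStringSet subseq
#'   reverseComplement
NULL

.EVENT_COLS <- c("event_id", "chrom", "start", "end", "strand", "host_gene",
                 "circ_type", "sample_id", "bsj", "fsj")

#' Read a circRNA event/count table
#'
#' Reads a tab-separated table with one row per (event, sample) quantification
#' and the header columns \code{event_id, chrom, start, end, strand,
#' host_gene, circ_type, sample_id, bsj, fsj} (the column set emitted by
#' BSJ-aware circRNA quantifiers).  Coordinates are 1-based closed, spanning
#' the back-splicing junction.
#'
#' @param path path to the TSV file.
#' @param ratio_c junction-ratio convention passed to
#'   \code{\link{junctionRatio}} (default 2).
#' @return list with \code{events} (a \code{\link{CircEventSet}} of unique
#'   events) and \code{counts} (data.frame: event_id, sample_id, bsj, fsj,
#'   ratio).
#' @export
readEventTable <- function(path, ratio_c = 2) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(.EVENT_COLS, colnames(df))
  if (length(miss))
    stop("event table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(list(events = CircEventSet(character(), character(), integer(),
                                      integer(), character())[0],
                counts = data.frame(event_id = character(),
                                    sample_id = character(),
                                    bsj = integer(), fsj = integer(),
                                    ratio = numeric())))
  # +1 for header: report file line numbers for bad rows
  bad <- which(!is.finite(df$bsj) | !is.finite(df$fsj) |
                 df$bsj < 0 | df$fsj < 0)
  if (length(bad))
    stop("event table validation error: negative or non-numeric counts on ",
         "line(s) ", paste(bad + 1L, collapse = ", "))
  bad <- which(df$start > df$end)
  if (length(bad))
    stop("event table validation error: start > end on line(s) ",
         paste(bad + 1L, collapse = ", "))
  first <- !duplicated(df$event_id)
  ev <- CircEventSet(df$event_id[first], df$chrom[first], df$start[first],
                     df$end[first], df$strand[first], df$host_gene[first],
                     df$circ_type[first])
  counts <- data.frame(event_id = df$event_id, sample_id = df$sample_id,
                       bsj = as.integer(df$bsj), fsj = as.integer(df$fsj),
                       stringsAsFactors = FALSE)
  counts$ratio <- junctionRatio(counts$bsj, counts$fsj, c = ratio_c)
  list(events = ev, counts = counts)
}

#' Write a circRNA event/count table
#'
#' Inverse of \code{\link{readEventTable}}: numeric fields round-trip
#' bit-exactly.
#'
#' @param events a \code{CircEventSet}.
#' @param counts data.frame as returned by \code{readEventTable}.
#' @param path output path.
#' @export
writeEventTable <- function(events, counts, path) {
  gr <- eventRanges(events)
  idx <- match(counts$event_id, gr$event_id)
  if (anyNA(idx)) stop("counts reference unknown event_id(s)")
  out <- data.frame(event_id = counts$event_id,
                    chrom = as.character(seqnames(gr))[idx],
                    start = start(gr)[idx], end = end(gr)[idx],
                    strand = as.character(strand(gr))[idx],
                    host_gene = gr$host_gene[idx],
                    circ_type = gr$circ_type[idx],
                    sample_id = counts$sample_id,
                    bsj = counts$bsj, fsj = counts$fsj,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pivot long counts into a JunctionCountSet
#'
#' @param counts data.frame with event_id, sample_id, bsj, fsj.
#' @return a \code{\link{JunctionCountSet}} (\code{NA} where an event was not
#'   quantified in a sample).
#' @export
countsToMatrix <- function(counts) {
  ev <- unique(counts$event_id); sm <- unique(counts$sample_id)
  b <- f <- matrix(NA_integer_, length(ev), length(sm),
                   dimnames = list(ev, sm))
  i <- cbind(match(counts$event_id, ev), match(counts$sample_id, sm))
  b[i] <- counts$bsj; f[i] <- counts$fsj
  JunctionCountSet(b, f)
}

#' Read a gene x sample expression matrix (TPM-like TSV)
#'
#' First column = gene symbol, remaining columns = samples.  Duplicate gene
#' ids or negative values are errors.
#'
#' @param path path to the TSV.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression matrix")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  rownames(m) <- genes
  m
}

#' Write / read a max-abs normalizer
#'
#' Persisted as TSV (feature, max_abs, constant).
#' @param norm a \code{\link{MaxAbsNormalizer-class}} object.
#' @param path file path.
#' @return \code{readNormalizer} returns a \code{MaxAbsNormalizer}.
#' @export
writeNormalizer <- function(norm, path) {
  write.table(data.frame(feature = names(norm@max_abs),
                         max_abs = norm@max_abs,
                         constant = norm@constant),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNormalizer
#' @export
readNormalizer <- function(path) {
  df <- read.delim(path, sep = "\t")
  mx <- df$max_abs; names(mx) <- df$feature
  ct <- as.logical(df$constant); names(ct) <- df$feature
  new("MaxAbsNormalizer", max_abs = mx, constant = ct)
}

#' Read a per-base score track
#'
#' Accepts a 4-column TSV (\code{chrom, start, end, score}; 1-based closed)
#' or a bigWig file (extension \code{.bw}/\code{.bigwig}).
#'
#' @param path input file.
#' @param fill value for uncovered bases.
#' @return a \code{\link{ScoreTrack-class}} object.
#' @export
readScoreTrack <- function(path, fill = 0) {
  if (grepl("\\.(bw|bigwig)$", tolower(path))) {
    gr <- rtracklayer::import(path)
  } else {
    df <- read.delim(path, header = TRUE, sep = "\t")
    need <- c("chrom", "start", "end", "score")
    if (!all(need %in% colnames(df)))
      stop("score track TSV needs columns: ", paste(need, collapse = ", "))
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), score = df$score)
  }
  ScoreTrack(gr, fill = fill)
}

#' Per-base values of a ScoreTrack over an interval
#'
#' @param track a \code{ScoreTrack}.
#' @param chrom,start,end 1-based closed query interval.
#' @return list with \code{values} (length \code{end-start+1}; fill where
#'   uncovered) and \code{covered} (logical, same length).
#' @export
trackValues <- function(track, chrom, start, end) {
  w <- end - start + 1L
  vals <- rep(track@fill, w)
  cov <- rep(FALSE, w)
  q <- GRanges(chrom, IRanges(start, end))
  hits <- findOverlaps(track@intervals, q)
  for (h in S4Vectors::queryHits(hits)) {
    iv <- track@intervals[h]
    lo <- max(start(iv), start) - start + 1L
    hi <- min(end(iv), end) - start + 1L
    vals[lo:hi] <- iv$score
    cov[lo:hi] <- TRUE
  }
  list(values = vals, covered = cov)
}

#' Read exon annotation from GTF/GFF
#'
#' Keeps \code{exon} records; exon rank within each transcript is recomputed
#' in transcript (strand-aware) orientation.
#'
#' @param path GTF/GFF3 file.
#' @return \code{GRanges} of exons with \code{gene_id}, \code{transcript_id}
#'   and \code{exon_rank} metadata.
#' @export
readExonsGtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon records in ", path)
  ord <- order(gr$transcript_id, ifelse(as.character(strand(gr)) == "-",
                                        -start(gr), start(gr)))
  gr <- gr[ord]
  gr$exon_rank <- unlist(lapply(split(seq_along(gr), gr$transcript_id)[
    unique(gr$transcript_id)], seq_along), use.names = FALSE)
  gr
}

#' Read a repeat annotation BED
#'
#' BED name field carries the repeat family; anything other than
#' Alu/L1/L2 is mapped to \code{"other"}.
#'
#' @param path BED file.
#' @return \code{GRanges} with a \code{family} column.
#' @export
readRepeatsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  fam <- if (!is.null(gr$name)) gr$name else rep("other", length(gr))
  fam[!fam %in% c("Alu", "L1", "L2")] <- "other"
  gr$family <- fam
  gr
}

#' Read a genome FASTA into a DNAStringSet
#'
#' @param path FASTA file (names truncated at first whitespace).
#' @return \code{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*", "", names(g))
  g
}

#' Extract a sense-strand region sequence
#'
#' Coordinates are 1-based closed on the reference; for minus-strand queries
#' the reverse complement is returned, so the result always reads 5'->3' on
#' the host gene's sense strand.
#'
#' @param genome a \code{DNAStringSet}.
#' @param chrom,start,end interval.
#' @param strand \code{"+"} or \code{"-"}.
#' @return a \code{DNAString}.
#' @export
getRegionSeq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown sequence: ", chrom)
  n <- length(genome[[chrom]])
  if (start < 1L || end > n)
    stop("query [", start, ",", end, "] outside 1..", n, " on ", chrom)
  s <- subseq(genome[[chrom]], start, end)
  if (strand == "-") s <- reverseComplement(s)
  s
}

#' Read an IUPAC motif table (TSV: name, motif)
#'
#' @param path TSV with columns \code{name} and \code{motif}.
#' @return named character vector suitable for \code{\link{MotifRegistry}}.
#' @export
readMotifTable <- function(path) {
  df <- read.delim(path, sep = "\t")
  if (!all(c("name", "motif") %in% colnames(df)))
    stop("motif table needs columns name, motif")
  stats::setNames(toupper(chartr("U", "T", df$motif)), df$name)
}

#' Read position-specific scoring matrices from a text file
#'
#' Format: blocks starting with \code{>name}, followed by 4 whitespace-
#' separated rows of equal length giving log2-odds scores for A, C, G, T/U.
#'
#' @param path PSSM text file.
#' @return named list of 4 x w matrices (rows A, C, G, T).
#' @export
readPssmFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PSSM blocks (>name) in ", path)
  out <- list()
  for (k in seq_along(heads)) {
    nm <- sub("^>\\s*", "", lines[heads[k]])
    stop_at <- if (k < length(heads)) heads[k + 1L] - 1L else length(lines)
    rows <- lines[(heads[k] + 1L):stop_at]
    if (length(rows) != 4L) stop("PSSM '", nm, "' must have 4 rows")
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    rownames(m) <- c("A", "C", "G", "T")
    out[[nm]] <- m
  }
  out
}

#' Read a k-mer catalog (one k-mer per line)
#'
#' Used for exon/intron splicing enhancer and silencer sets.
#'
#' @param path text file, one k-mer per line; lines starting with '#' skipped.
#' @return character vector of upper-case DNA k-mers.
#' @export
readKmerCatalog <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!grepl("^#", x)])
  toupper(chartr("U", "T", x[nzchar(x)]))
}
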