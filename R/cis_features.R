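#' @importFrom Biostrings countPattern oligonucleotideFrequency xscat
NULL

.STOPS <- c("TAA", "TAG", "TGA")

#' Transcript-structure features of a circRNA event
#'
#' Lengths of the flanking introns (I1/I2) and BSJ exons (A1/A2), the BSJ
#' span, the ratio of spliced circRNA length to span, and a frameshift
#' indicator (1 when the summed circularised exon length is not a multiple
#' of 3).  Absent regions contribute 0 plus a companion missingness
#' indicator.
#'
#' @param events resolved \code{\link{CircEventSet}}.
#' @param i event index.
#' @param exons exon annotation (for the spliced length).
#' @return named numeric vector.
#' @export
structureFeatures <- function(events, i, exons) {
  gr <- eventRanges(events)
  if (!isTRUE(gr$resolved[i])) stop("event anatomy not resolved")
  ivlen <- function(region) {
    iv <- .anatomyInterval(gr, i, region)
    if (is.null(iv)) 0 else unname(iv["end"] - iv["start"] + 1)
  }
  tx <- gr$transcript_id[i]
  idx <- which(exons$transcript_id == tx &
                 start(exons) >= start(gr)[i] & end(exons) <= end(gr)[i])
  spliced_len <- sum(width(exons)[idx])
  span <- width(gr)[i]
  c(len_i1 = ivlen("I1"), len_i2 = ivlen("I2"),
    len_a1 = ivlen("A1"), len_a2 = ivlen("A2"),
    bsj_span = span,
    spliced_len = spliced_len,
    spliced_span_ratio = spliced_len / span,
    frameshift = as.numeric(spliced_len %% 3 != 0),
    miss_i1 = as.numeric(is.null(.anatomyInterval(gr, i, "I1"))),
    miss_i2 = as.numeric(is.null(.anatomyInterval(gr, i, "I2"))),
    miss_c1 = as.numeric(gr$c1_missing[i]),
    miss_c2 = as.numeric(gr$c2_missing[i]))
}

#' Translatability of a circular sequence
#'
#' For each reading frame offset 0/1/2, reads codons around one full pass of
#' the circle (codon starts within the first pass, wrapping across the BSJ)
#' and flags 1 when no stop codon (TAA/TAG/TGA) is met.
#'
#' @param circ_seq spliced circular sequence (character or \code{DNAString}),
#'   sense strand.
#' @return numeric vector \code{c(frame0, frame1, frame2)} of 0/1 flags.
#' @export
translatability <- function(circ_seq) {
  s <- toupper(as.character(circ_seq))
  L <- nchar(s)
  out <- c(frame0 = 0, frame1 = 0, frame2 = 0)
  if (L < 3L) {
    warning("sequence shorter than 3 nt; translatability flags set to 0")
    return(out)
  }
  doubled <- paste0(s, s)
  for (f in 0:2) {
    starts <- seq.int(f + 1L, L, by = 3L)
    codons <- substring(doubled, starts, starts + 2L)
    out[f + 1L] <- as.numeric(!any(codons %in% .STOPS))
  }
  out
}

#' Splice-site strength from a probability PWM
#'
#' Log2 odds of the position weight matrix against a uniform background,
#' summed over positions.  Non-ACGT bases score as background (0
#' contribution).
#'
#' @param context site context sequence, length must equal \code{ncol(pwm)}
#'   (9 for donors: 3 exonic + 6 intronic; 23 for acceptors: 20 intronic +
#'   3 exonic).
#' @param pwm 4 x w probability matrix, rows A, C, G, T.
#' @return log2-odds score (bits).
#' @export
spliceSiteStrength <- function(context, pwm) {
  s <- strsplit(toupper(as.character(context)), "")[[1L]]
  if (length(s) != ncol(pwm))
    stop("context length ", length(s), " != PWM width ", ncol(pwm))
  ri <- match(s, c("A", "C", "G", "T"))
  p <- ifelse(is.na(ri), 0.25, pwm[cbind(ri, seq_along(s))])
  sum(log2(p / 0.25))
}

# donor/acceptor context sequences at an exon boundary, sense strand.
# site = "donor": last 3 exonic + first 6 intronic bases (9-mer);
# site = "acceptor": last 20 intronic + first 3 exonic bases (23-mer).
.siteContext <- function(genome, chrom, strand, exon_start, exon_end, site) {
  if (site == "donor") {
    if (strand == "+") { s <- exon_end - 2L; e <- exon_end + 6L }
    else { s <- exon_start - 6L; e <- exon_start + 2L }
  } else {
    if (strand == "+") { s <- exon_start - 20L; e <- exon_start + 2L }
    else { s <- exon_end - 2L; e <- exon_end + 20L }
  }
  n <- length(genome[[chrom]])
  if (s < 1L || e > n) return(NULL)      # context overruns contig edge
  getRegionSeq(genome, chrom, s, e, strand)
}

#' Splice-site strength features for an event
#'
#' Scores the canonical donor/acceptor contexts of the C1-A1 and A2-C2
#' junctions (the back-splice site reuses the A2 donor and A1 acceptor
#' contexts).  Missing regions or contexts overrunning the contig edge give
#' 0 with a missing flag.
#'
#' @param events resolved \code{CircEventSet}; \code{i} event index.
#' @param i event index.
#' @param genome \code{DNAStringSet}.
#' @param donor_pwm,acceptor_pwm probability PWMs (4 x 9 and 4 x 23).
#' @return named numeric vector of 4 scores + 4 missing flags.
#' @export
spliceSiteFeatures <- function(events, i, genome, donor_pwm, acceptor_pwm) {
  gr <- eventRanges(events)
  chrom <- as.character(seqnames(gr))[i]
  str_i <- as.character(strand(gr))[i]
  one <- function(region, site, pwm) {
    iv <- .anatomyInterval(gr, i, region)
    if (is.null(iv)) return(c(NA_real_))
    ctx <- .siteContext(genome, chrom, str_i, iv["start"], iv["end"], site)
    if (is.null(ctx)) return(NA_real_)
    spliceSiteStrength(ctx, pwm)
  }
  v <- c(ss_donor_c1 = one("C1", "donor", donor_pwm),
         ss_acceptor_a1 = one("A1", "acceptor", acceptor_pwm),
         ss_donor_a2 = one("A2", "donor", donor_pwm),
         ss_acceptor_c2 = one("C2", "acceptor", acceptor_pwm))
  flags <- as.numeric(is.na(v)); names(flags) <- paste0(names(v), "_miss")
  v[is.na(v)] <- 0
  c(v, flags)
}

#' Windowed score-track features
#'
#' Aggregates a per-base track over windows anchored at region ends.  The
#' window plan enumerates (region, end = first/last, width, agg = mean/max);
#' "first"/"last" are transcript-oriented.  Windows truncated at region
#' boundaries aggregate the available bases; regions absent or fully
#' uncovered give the track fill value plus a flag.
#'
#' @param events resolved \code{CircEventSet}; \code{i} event index.
#' @param i event index.
#' @param track a \code{\link{ScoreTrack-class}} object.
#' @param plan data.frame with columns \code{region}, \code{end},
#'   \code{width}, \code{agg}.
#' @param prefix name prefix for the returned features.
#' @return named numeric vector (one value + one missing flag per window).
#' @export
trackWindowFeatures <- function(events, i, track, plan, prefix = "trk") {
  if (any(plan$width <= 0)) stop("window width must be positive")
  gr <- eventRanges(events)
  chrom <- as.character(seqnames(gr))[i]
  str_i <- as.character(strand(gr))[i]
  vals <- flags <- numeric(nrow(plan))
  nms <- paste0(prefix, "_", tolower(plan$region), "_", plan$end, "_",
                plan$agg, plan$width)
  for (k in seq_len(nrow(plan))) {
    iv <- .anatomyInterval(gr, i, plan$region[k])
    if (is.null(iv)) { vals[k] <- track@fill; flags[k] <- 1; next }
    w <- min(plan$width[k], iv["end"] - iv["start"] + 1)
    first_genomic <- (plan$end[k] == "first") == (str_i == "+")
    if (first_genomic) { s <- iv["start"]; e <- iv["start"] + w - 1 }
    else { s <- iv["end"] - w + 1; e <- iv["end"] }
    tv <- trackValues(track, chrom, s, e)
    if (!any(tv$covered)) { vals[k] <- track@fill; flags[k] <- 1; next }
    x <- tv$values[tv$covered]
    vals[k] <- if (plan$agg[k] == "max") max(x) else mean(x)
  }
  stats::setNames(c(vals, flags), c(nms, paste0(nms, "_miss")))
}

#' Overlapping k-mer counts of a sequence
#'
#' @param seq character or \code{DNAString}.
#' @param k k-mer size, 1..8.
#' @return named integer vector over all 4^k DNA k-mers.
#' @export
kmerCounts <- function(seq, k = 3) {
  if (k < 1 || k > 8) stop("k must be in 1..8")
  s <- DNAString(toupper(as.character(seq)))
  if (length(s) < k)
    return(oligonucleotideFrequency(DNAString(""), width = k))
  oligonucleotideFrequency(s, width = k)
}

#' Total catalog hits (overlapping) in a sequence
#'
#' @param seq character or \code{DNAString}.
#' @param catalog character vector of k-mers (e.g. an ESE/ESS set).
#' @return integer, summed overlapping occurrence count.
#' @export
catalogHits <- function(seq, catalog) {
  s <- DNAString(toupper(as.character(seq)))
  sum(vapply(catalog, function(p) {
    if (length(s) < nchar(p)) 0L else countPattern(p, s)
  }, integer(1)))
}

#' k-mer and splicing enhancer/silencer features
#'
#' k-mer spectra of the first and last 150 bp of each flanking intron
#' (transcript-oriented; shorter introns are counted over their available
#' length) and enhancer/silencer catalog hit counts: exonic catalogs over
#' A1/A2, intronic catalogs over the same intron-end windows.
#'
#' @param i1_seq,i2_seq flanking intron sequences (sense strand), or
#'   \code{NULL} when absent.
#' @param a1_seq,a2_seq BSJ exon sequences.
#' @param catalogs list with character vectors \code{ese}, \code{ess},
#'   \code{ise}, \code{iss}.
#' @param k k-mer size (default 3).
#' @param window intron end-window width (default 150).
#' @return named numeric vector.
#' @export
kmerEseFeatures <- function(i1_seq, i2_seq, a1_seq, a2_seq, catalogs,
                            k = 3, window = 150) {
  if (k < 1 || k > 8) stop("k must be in 1..8")
  endWindows <- function(s) {
    if (is.null(s)) return(list(first = NULL, last = NULL))
    x <- as.character(s); L <- nchar(x); w <- min(window, L)
    list(first = substr(x, 1L, w), last = substr(x, L - w + 1L, L))
  }
  w1 <- endWindows(i1_seq); w2 <- endWindows(i2_seq)
  km <- function(s, tag) {
    v <- if (is.null(s)) kmerCounts(paste(rep("A", 0), collapse = ""), k) * 0
         else kmerCounts(s, k)
    stats::setNames(as.numeric(v), paste0("kmer_", tag, "_", names(v)))
  }
  hits <- function(s, cat) if (is.null(s)) 0 else catalogHits(s, cat)
  c(km(w1$first, "i1_first"), km(w1$last, "i1_last"),
    km(w2$first, "i2_first"), km(w2$last, "i2_last"),
    ese_a1 = hits(a1_seq, catalogs$ese), ese_a2 = hits(a2_seq, catalogs$ese),
    ess_a1 = hits(a1_seq, catalogs$ess), ess_a2 = hits(a2_seq, catalogs$ess),
    ise_i1 = hits(w1$first, catalogs$ise) + hits(w1$last, catalogs$ise),
    ise_i2 = hits(w2$first, catalogs$ise) + hits(w2$last, catalogs$ise),
    iss_i1 = hits(w1$first, catalogs$iss) + hits(w1$last, catalogs$iss),
    iss_i2 = hits(w2$first, catalogs$iss) + hits(w2$last, catalogs$iss),
    miss_kmer_i1 = as.numeric(is.null(i1_seq)),
    miss_kmer_i2 = as.numeric(is.null(i2_seq)))
}

#' Scan a sequence with a log2-odds PSSM
#'
#' Scores every window of width \code{ncol(pssm)}; windows containing
#' non-ACGT bases take 0 at those positions.
#'
#' @param seq character or \code{DNAString}.
#' @param pssm 4 x w log2-odds matrix (rows A, C, G, T).
#' @param threshold windows scoring above this enter the sum (default 0).
#' @return list: \code{sum} of above-threshold window scores, \code{n}
#'   windows scored, \code{scores} per-window vector.
#' @export
pssmScan <- function(seq, pssm, threshold = 0) {
  s <- strsplit(toupper(as.character(seq)), "")[[1L]]
  w <- ncol(pssm); L <- length(s)
  if (L < w) return(list(sum = 0, n = 0L, scores = numeric()))
  ri <- match(s, c("A", "C", "G", "T"))
  contrib <- matrix(0, 4L + 1L, L)   # row 5: unknown base scores 0
  contrib[cbind(ifelse(is.na(ri), 5L, ri), seq_len(L))] <- 1
  sc <- vapply(seq_len(L - w + 1L), function(p) {
    idx <- ri[p:(p + w - 1L)]
    sum(ifelse(is.na(idx), 0, pssm[cbind(idx, seq_len(w))]))
  }, numeric(1))
  keep <- sc > threshold
  list(sum = sum(sc[keep]), n = L - w + 1L, scores = sc)
}

#' RBP motif and PSSM features
#'
#' IUPAC motif occurrence counts per motif and region, plus per-PSSM summed
#' above-threshold scores over each flanking intron and the same normalised
#' by intron length.
#'
#' @param region_seqs named list of sense-strand sequences over (a subset
#'   of) \code{A1, A2, C1, C2, I1, I2}; absent regions \code{NULL}.
#' @param registry a \code{\link{MotifRegistry-class}} object.
#' @param pssm_threshold log2-odds threshold for PSSM windows (default 0).
#' @return named numeric vector.
#' @export
rbpMotifFeatures <- function(region_seqs, registry, pssm_threshold = 0) {
  if (!length(registry@motifs) && !length(registry@pssms))
    stop("empty motif registry")
  regions <- c("I1", "I2", "A1", "A2", "C1", "C2")
  out <- numeric()
  for (r in regions) {
    s <- region_seqs[[r]]
    d <- if (is.null(s)) NULL else DNAString(toupper(as.character(s)))
    for (m in names(registry@motifs)) {
      pat <- registry@motifs[[m]]
      cnt <- if (is.null(d) || length(d) < nchar(pat)) 0 else
        countPattern(pat, d, fixed = FALSE)
      out[paste0("motif_", m, "_", tolower(r))] <- cnt
    }
  }
  for (r in c("I1", "I2")) {
    s <- region_seqs[[r]]
    L <- if (is.null(s)) 0L else nchar(as.character(s))
    for (p in names(registry@pssms)) {
      sc <- if (L == 0L) 0 else
        pssmScan(s, registry@pssms[[p]], pssm_threshold)$sum
      out[paste0("pssm_", p, "_", tolower(r))] <- sc
      out[paste0("pssm_", p, "_", tolower(r), "_norm")] <-
        if (L > 0L) sc / L else 0
    }
  }
  out
}

#' Repeat-element counts in flanking introns
#'
#' Counts repeat records overlapping each flanking intron by at least 1 bp,
#' per family (Alu, L1, L2, other).
#'
#' @param events resolved \code{CircEventSet}; \code{i} event index.
#' @param i event index.
#' @param repeats \code{GRanges} with a \code{family} column
#'   (see \code{\link{readRepeatsBed}}).
#' @return named numeric vector.
#' @export
repeatFeatures <- function(events, i, repeats) {
  gr <- eventRanges(events)
  fams <- c("Alu", "L1", "L2", "other")
  out <- numeric()
  for (r in c("I1", "I2")) {
    iv <- .anatomyInterval(gr, i, r)
    cnts <- stats::setNames(numeric(length(fams)), fams)
    if (!is.null(iv) && length(repeats)) {
      q <- GRanges(as.character(seqnames(gr))[i],
                   IRanges(iv["start"], iv["end"]))
      ov <- repeats[S4Vectors::queryHits(findOverlaps(repeats, q,
                                                      minoverlap = 1L))]
      tb <- table(factor(ov$family, levels = fams))
      cnts[names(tb)] <- as.numeric(tb)
    }
    names(cnts) <- paste0("rep_", tolower(fams), "_", tolower(r))
    out <- c(out, cnts)
  }
  out
}

# merged reverse-complementary matches between x and y:
# exact seeds of length >= word_size between x and reverseComplement(y),
# overlapping seeds on the same diagonal merged into one match.
.rcmCount <- function(x, y, word_size) {
  x <- toupper(as.character(x)); y <- toupper(as.character(y))
  ry <- as.character(reverseComplement(DNAString(y)))
  nx <- nchar(x); nyr <- nchar(ry); w <- word_size
  if (nx < w || nyr < w) return(0L)
  kx <- substring(x, 1:(nx - w + 1L), w:nx)
  ky <- substring(ry, 1:(nyr - w + 1L), w:nyr)
  pos_by_kmer <- split(seq_along(ky), ky)
  hits_i <- hits_j <- integer()
  for (i in seq_along(kx)) {
    js <- pos_by_kmer[[kx[i]]]
    if (!is.null(js)) {
      hits_i <- c(hits_i, rep.int(i, length(js)))
      hits_j <- c(hits_j, js)
    }
  }
  if (!length(hits_i)) return(0L)
  d <- hits_i - hits_j
  total <- 0L
  for (dg in unique(d)) {
    ii <- sort(hits_i[d == dg])
    # overlapping seeds (start within w-1 of the previous start) merge
    total <- total + 1L + sum(diff(ii) > (w - 1L))
  }
  total
}

#' Reverse-complementary match (RCM) features
#'
#' An RCM seed is an exact match of length >= \code{word_size} between one
#' intron and the reverse complement of the other (or itself); overlapping
#' seeds on the same alignment diagonal count as a single match.  Returns
#' cross-intron (I1 vs I2) and within-intron (I1 vs I1, I2 vs I2) counts and
#' each count divided by the summed intron length.
#'
#' @param i1_seq,i2_seq flanking intron sequences (sense strand) or
#'   \code{NULL}.
#' @param word_size exact seed length (default 11; must be >= 4).
#' @return named numeric vector (counts, length-weighted counts, missing
#'   flag).
#' @export
rcmFeatures <- function(i1_seq, i2_seq, word_size = 11) {
  if (word_size < 4) stop("word_size must be >= 4")
  miss <- is.null(i1_seq) || is.null(i2_seq)
  L <- 0
  if (!is.null(i1_seq)) L <- L + nchar(as.character(i1_seq))
  if (!is.null(i2_seq)) L <- L + nchar(as.character(i2_seq))
  cnt <- function(a, b) {
    if (is.null(a) || is.null(b)) 0L else .rcmCount(a, b, word_size)
  }
  cross <- cnt(i1_seq, i2_seq)
  w11 <- cnt(i1_seq, i1_seq)
  w22 <- cnt(i2_seq, i2_seq)
  norm <- function(v) if (L > 0) v / L else 0
  c(rcm_i1_i2 = cross, rcm_i1_i1 = w11, rcm_i2_i2 = w22,
    rcm_i1_i2_norm = norm(cross), rcm_i1_i1_norm = norm(w11),
    rcm_i2_i2_norm = norm(w22), rcm_miss = as.numeric(miss))
}

#' Splicing amount as counts per million
#'
#' CPM of junction reads supporting a gene's splicing in one sample.  Not
#' part of the three-class model's input.
#'
#' @param junction_reads junction read count (vectorised).
#' @param library_size total library size (> 0).
#' @return CPM value(s).
#' @export
splicingAmount <- function(junction_reads, library_size) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  junction_reads / library_size * 1e6
}

#' Default windowed-track plans
#'
#' Conservation: mean of the first and last 100 nt of I1 and I2.
#' Nucleosome occupancy: mean of the first and last 100 nt of I1/I2 and of
#' the first and last 50 nt of A1/A2.  Secondary structure: mean and max of
#' 20 nt windows flanking the two BSJ boundaries (the first/last 20 nt of A1
#' and A2).
#'
#' @return named list of window-plan data.frames keyed \code{conservation},
#'   \code{nucleosome}, \code{structure}.
#' @export
defaultTrackPlans <- function() {
  cons <- expand.grid(region = c("I1", "I2"), end = c("first", "last"),
                      width = 100, agg = "mean", stringsAsFactors = FALSE)
  nuc <- rbind(cons,
               expand.grid(region = c("A1", "A2"), end = c("first", "last"),
                           width = 50, agg = "mean",
                           stringsAsFactors = FALSE))
  sec <- expand.grid(region = c("A1", "A2"), end = c("first", "last"),
                     width = 20, agg = c("mean", "max"),
                     stringsAsFactors = FALSE)
  list(conservation = cons, nucleosome = nuc, structure = sec)
}

#' Load the shipped default cis registries
#'
#' Reads the illustrative default motif set, synthetic PSSMs,
#' enhancer/silencer catalogs and splice-site PWMs from the package's
#' \code{extdata}.  All of them are pluggable: real analyses should supply
#' curated registries through the same readers.
#'
#' @return list: \code{motifs} (a \code{MotifRegistry}), \code{catalogs}
#'   (ese/ess/ise/iss), \code{donor_pwm}, \code{acceptor_pwm} (probability
#'   matrices).
#' @export
defaultRegistries <- function() {
  p <- function(f) system.file("extdata", "registry_default", f,
                               package = "circDSC", mustWork = TRUE)
  list(motifs = MotifRegistry(readMotifTable(p("motifs.tsv")),
                              readPssmFile(p("pssms_synthetic.txt"))),
       catalogs = list(ese = readKmerCatalog(p("ese.txt")),
                       ess = readKmerCatalog(p("ess.txt")),
                       ise = readKmerCatalog(p("ise.txt")),
                       iss = readKmerCatalog(p("iss.txt"))),
       donor_pwm = readPssmFile(p("donor_pwm.txt"))[["donor"]],
       acceptor_pwm = readPssmFile(p("acceptor_pwm.txt"))[["acceptor"]])
}

#' Extract the full cis feature matrix for resolved events
#'
#' Concatenates, per event: transcript structure, translatability,
#' splice-site strength, conservation / secondary-structure / nucleosome
#' track windows, splicing enhancer-silencer and k-mer counts, RBP motif and
#' PSSM features, repeat counts, and RCM features.  Feature order is fixed
#' by the first event and identical for all rows.  Splicing amount is
#' per-sample and is appended at pair-assembly time, not here.
#'
#' @param events resolved \code{CircEventSet}.
#' @param genome \code{DNAStringSet}.
#' @param exons exon annotation \code{GRanges}.
#' @param motifs a \code{MotifRegistry}.
#' @param catalogs list of ese/ess/ise/iss k-mer vectors.
#' @param donor_pwm,acceptor_pwm probability PWMs.
#' @param tracks named list of \code{ScoreTrack}s (any subset of
#'   \code{conservation}, \code{nucleosome}, \code{structure}).
#' @param repeats repeat \code{GRanges} (may be empty).
#' @param k k-mer size; \code{word_size} RCM seed length.
#' @param word_size RCM seed length (default 11).
#' @return numeric matrix, resolved events x features, with a
#'   \code{"registry"} attribute (data.frame name/category).
#' @export
cisFeatureMatrix <- function(events, genome, exons, motifs, catalogs,
                             donor_pwm, acceptor_pwm,
                             tracks = list(), repeats = GRanges(),
                             k = 3, word_size = 11) {
  gr <- eventRanges(events)
  keep <- which(gr$resolved)
  if (!length(keep)) stop("no resolved events")
  plans <- defaultTrackPlans()
  rows <- vector("list", length(keep))
  for (jj in seq_along(keep)) {
    i <- keep[jj]
    seqs <- lapply(stats::setNames(nm = c("A1", "A2", "C1", "C2", "I1", "I2")),
                   function(r) regionSeq(events, i, r, genome))
    v <- c(structureFeatures(events, i, exons),
           stats::setNames(translatability(circularSeq(events, i, exons,
                                                       genome)),
                           c("transl_frame0", "transl_frame1",
                             "transl_frame2")),
           spliceSiteFeatures(events, i, genome, donor_pwm, acceptor_pwm))
    for (tn in names(plans)) {
      if (!is.null(tracks[[tn]]))
        v <- c(v, trackWindowFeatures(events, i, tracks[[tn]], plans[[tn]],
                                      prefix = tn))
    }
    v <- c(v,
           kmerEseFeatures(seqs$I1, seqs$I2, seqs$A1, seqs$A2, catalogs,
                           k = k),
           rbpMotifFeatures(seqs, motifs),
           repeatFeatures(events, i, repeats),
           rcmFeatures(seqs$I1, seqs$I2, word_size = word_size))
    rows[[jj]] <- v
  }
  nm <- names(rows[[1L]])
  bad <- which(vapply(rows, function(r) !identical(names(r), nm), logical(1)))
  if (length(bad)) stop("inconsistent feature registry across events")
  m <- do.call(rbind, rows)
  rownames(m) <- gr$event_id[keep]
  attr(m, "registry") <- data.frame(
    name = nm,
    category = .featureCategory(nm),
    stringsAsFactors = FALSE)
  m
}

.featureCategory <- function(nm) {
  cat <- rep("structure", length(nm))
  cat[grepl("^transl_", nm)] <- "translatability"
  cat[grepl("^ss_", nm)] <- "splice_strength"
  cat[grepl("^conservation_", nm)] <- "conservation"
  cat[grepl("^structure_", nm)] <- "secondary_structure"
  cat[grepl("^nucleosome_", nm)] <- "nucleosome"
  cat[grepl("^(ese|ess|ise|iss)_", nm)] <- "ese_ess"
  cat[grepl("^(kmer|miss_kmer)_", nm)] <- "kmer"
  cat[grepl("^(motif|pssm)_", nm)] <- "rbp_motif"
  cat[grepl("^rcm_", nm)] <- "rcm"
  cat[grepl("^rep_", nm)] <- "repeats"
  cat
}
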