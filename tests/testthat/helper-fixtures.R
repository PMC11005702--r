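# Shared fixtures: a deterministic toy genome with two 4-exon genes (one per
# strand), its GTF, and toy event/count tables.  Everything is generated in
# code at test time.

toyExonTable <- function() {
  # exon coordinates shared by both genes (1-based closed)
  data.frame(start = c(101L, 401L, 801L, 1201L),
             end = c(200L, 500L, 900L, 1300L))
}

toyGenome <- function(len = 2000L) {
  set.seed(424242)
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c(0.3, 0.2, 0.2, 0.3))
  ex <- toyExonTable()
  # canonical splice dinucleotides so site contexts are realistic
  for (i in seq_len(nrow(ex) - 1L)) {
    base[ex$end[i] + 1L:2L] <- c("G", "T")      # donor GT
    base[ex$start[i + 1L] - 2L:1L] <- c("A", "G") # acceptor AG
  }
  Biostrings::DNAStringSet(structure(paste(base, collapse = ""),
                                     names = "chr1"))
}

writeToyGtf <- function(path) {
  ex <- toyExonTable()
  lines <- character()
  for (g in list(list(gene = "GENEA", tx = "TX1", strand = "+"),
                 list(gene = "GENEB", tx = "TX2", strand = "-"))) {
    for (i in seq_len(nrow(ex))) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g$gene, g$tx)
      lines <- c(lines, paste("chr1", "toy", "exon", ex$start[i], ex$end[i],
                              ".", g$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  path
}

toyEvents <- function() {
  # ev_single: exon 2 only; ev_multi: exons 2-3; ev_minus: exons 2-3 on the
  # minus-strand gene; ev_first: exons 1-2 (no upstream exon on +)
  CircEventSet(event_id = c("ev_single", "ev_multi", "ev_minus", "ev_first"),
               chrom = "chr1",
               start = c(401L, 401L, 401L, 101L),
               end = c(500L, 900L, 900L, 500L),
               strand = c("+", "+", "-", "+"),
               host_gene = c("GENEA", "GENEA", "GENEB", "GENEA"),
               circ_type = "exonic")
}

resolvedToyEvents <- function(gtf_path = NULL) {
  path <- if (is.null(gtf_path)) withr::local_tempfile(fileext = ".gtf")
          else gtf_path
  writeToyGtf(path)
  resolveEventAnatomy(toyEvents(), readExonsGtf(path))
}

writeToyEventTable <- function(path,
                               bsj = c(10L, 0L, 7L),
                               fsj = c(20L, 5L, 0L)) {
  n <- length(bsj)
  df <- data.frame(event_id = sprintf("e%d", seq_len(n)),
                   chrom = rep("chr1", n), start = rep(401L, n),
                   end = rep(900L, n), strand = rep("+", n),
                   host_gene = rep("GENEA", n),
                   circ_type = rep("exonic", n),
                   sample_id = rep("S1", n), bsj = bsj, fsj = fsj)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small, fast synthetic corpus + dense model shared across module tests
smallSimConfig <- function(seed = 5L) {
  simConfig(n_events = 600L, n_samples = 16L, n_rbps = 20L, n_cis = 12L,
            seed = seed)
}

smallModelConfig <- function(head = "binary", seed = 2L, epochs = 4L) {
  modelConfig(head = head, widths = c(64L, 32L, 16L, 8L),
              dropout = c(0.3, 0.2, 0.1, 0.1), batch_size = 128L,
              epochs = epochs, seed = seed)
}

.fixture_env <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

smallCorpus <- function() memoFixture("small_corpus",
                                      simulateCorpus(smallSimConfig()))

smallBinaryFit <- function() memoFixture("small_binary_fit", {
  corpus <- smallCorpus()
  td <- pairTrainingData(corpus, head = "binary")
  model <- trainDenseModel(td$x, td$y, smallModelConfig("binary"))
  list(corpus = corpus, td = td, model = model)
})

smallThreeClassFit <- function() memoFixture("small_three_class_fit", {
  corpus <- smallCorpus()
  td <- pairTrainingData(corpus, head = "three_class")
  model <- trainDenseModel(td$x, td$y, smallModelConfig("three_class"))
  list(corpus = corpus, td = td, model = model)
})

# full-scale fixtures for the acceptance checks: the default-condition
# corpus (2000 events x 20 pairs), its labeled training data, and the
# 8-epoch binary model, all at fixed seeds
accCorpus <- function() memoFixture("acc_corpus",
                                    simulateCorpus(simConfig(seed = 7102L)))

accTraining <- function() memoFixture("acc_training",
                                      pairTrainingData(accCorpus(),
                                                       head = "binary"))

accModel <- function() memoFixture("acc_model", {
  td <- accTraining()
  trainDenseModel(td$x, td$y, modelConfig("binary", seed = 7103L))
})

# independent brute-force BHT oracle: full outer-product quadrature with
# fractional area weights at the |delta psi| = C boundary
bruteBht <- function(bA, fA, bB, fB, C = 0.05, conv = 2, m = 2001L,
                     q = NULL) {
  psis <- (seq_len(m) - 0.5) / m
  h <- 1 / m
  f <- psis / (conv - (conv - 1) * psis)
  la <- dbinom(bA, bA + fA, f, log = TRUE)
  lb <- dbinom(bB, bB + fB, f, log = TRUE)
  L <- exp(outer(la - max(la), lb - max(lb), "+"))
  Dm <- abs(outer(psis, psis, "-"))
  tri <- function(t) ifelse(t <= -1, 0,
                            ifelse(t >= 1, 1,
                                   ifelse(t < 0, (1 + t)^2 / 2,
                                          1 - (1 - t)^2 / 2)))
  W <- tri((Dm - C) / h) + tri((-Dm - C) / h)
  SD <- sum(L * W); SU <- sum(L * (1 - W))
  if (is.null(q)) return(SD / (SD + SU))
  nD <- sum(W); nU <- m^2 - nD
  num <- q * SD / nD
  num / (num + (1 - q) * SU / nU)
}

bhtBattery <- function() {
  data.frame(bA = c(0, 80, 5, 10, 3, 9, 50, 2, 100, 7,
                    40, 12, 0, 25, 6, 18, 33, 70, 4, 15),
             fA = c(200, 20, 95, 10, 30, 24, 50, 18, 0, 13,
                    360, 88, 150, 75, 54, 82, 67, 30, 96, 135),
             bB = c(0, 5, 80, 12, 9, 3, 25, 2, 0, 7,
                    10, 30, 5, 25, 18, 6, 60, 20, 4, 45),
             fB = c(200, 95, 20, 8, 24, 30, 75, 18, 100, 13,
                    390, 70, 145, 75, 42, 94, 40, 80, 96, 105))
}
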