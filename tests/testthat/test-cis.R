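gtfPath <- function() {
  f <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeToyGtf(f)
  f
}

test_that("structure features follow interval arithmetic and mod-3 rule", {
  gtf <- gtfPath()
  exons <- readExonsGtf(gtf)
  ev <- resolvedToyEvents(gtf)
  gr <- eventRanges(ev)
  i <- which(gr$event_id == "ev_multi")
  v <- structureFeatures(ev, i, exons)
  # exons 2+3 are 100 nt each, introns 200/300, span 500
  expect_equal(unname(v["len_i1"]), 200)
  expect_equal(unname(v["len_i2"]), 300)
  expect_equal(unname(v["spliced_len"]), 200)
  expect_equal(unname(v["spliced_span_ratio"]), 200 / 500)
  expect_equal(unname(v["frameshift"]), 1)   # 200 mod 3 = 2
  s <- structureFeatures(ev, which(gr$event_id == "ev_single"), exons)
  expect_equal(unname(s["frameshift"]), 1)   # 100 mod 3 = 1
  fe <- structureFeatures(ev, which(gr$event_id == "ev_first"), exons)
  expect_equal(unname(fe["miss_c1"]), 1)
  expect_equal(unname(fe["len_i1"]), 0)
  expect_error(structureFeatures(toyEvents(), 1, exons), "not resolved")
})

test_that("translatability scans codons around one circular pass", {
  expect_equal(unname(translatability("ATGGCAGCT")), c(1, 1, 1))
  # circular reading of TAA repeats hits a stop only in frame 0: the other
  # frames cycle through ATA codons forever (confirmed by the oracle below)
  expect_equal(unname(translatability("TAATAATAA")), c(0, 1, 1))
  # brute-force oracle on a doubled string
  bf <- function(s) {
    L <- nchar(s); d <- paste0(s, s)
    vapply(0:2, function(f) {
      starts <- seq(f + 1L, L, by = 3L)
      cods <- substring(d, starts, starts + 2L)
      as.numeric(!any(cods %in% c("TAA", "TAG", "TGA")))
    }, numeric(1))
  }
  for (s in c("ATGTAAGCC", "ATGGCAGCTA", "TTAGACCATA", "GGC")) {
    expect_equal(unname(translatability(s)), bf(s), info = s)
  }
  expect_warning(z <- translatability("AT"), "shorter")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("splice-site strength is log2 odds against uniform background", {
  uni <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(spliceSiteStrength("ACGTACGTA", uni), 0)
  cons <- matrix(1e-12, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons["G", ] <- 1
  expect_equal(spliceSiteStrength(paste(rep("G", 9), collapse = ""), cons),
               9 * log2(4))
  half <- matrix(c(0.5, 0.5, 1e-12, 1e-12), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(spliceSiteStrength("A", half), 1)
  expect_equal(spliceSiteStrength("N", half), 0)  # background at unknowns
  reg <- defaultRegistries()
  ev <- resolvedToyEvents()
  ss <- spliceSiteFeatures(ev, 2L, toyGenome(), reg$donor_pwm,
                           reg$acceptor_pwm)
  expect_equal(length(ss), 8L)
  expect_true(all(ss[grep("_miss$", names(ss))] == 0))
})

test_that("track windows aggregate, truncate and flag as planned", {
  ev <- resolvedToyEvents()
  gr <- eventRanges(ev)
  i <- which(gr$event_id == "ev_single")
  # constant track over everything
  tr7 <- ScoreTrack(GenomicRanges::GRanges("chr1",
                                           IRanges::IRanges(1, 2000),
                                           score = 7))
  plan <- data.frame(region = "I1", end = "first", width = 100,
                     agg = c("mean", "max"))
  v <- trackWindowFeatures(ev, i, tr7, plan)
  expect_equal(unname(v[1:2]), c(7, 7))
  # ramp 1..100 over the first intron window (I1 = 201..400 on +)
  ramp <- ScoreTrack(GenomicRanges::GRanges("chr1",
                                            IRanges::IRanges(201:300, 201:300),
                                            score = 1:100))
  v2 <- trackWindowFeatures(ev, i, ramp,
                            data.frame(region = "I1", end = "first",
                                       width = 100, agg = "mean"))
  expect_equal(unname(v2[1]), 50.5)
  # window wider than the region truncates to available bases
  v3 <- trackWindowFeatures(ev, i, tr7,
                            data.frame(region = "I1", end = "first",
                                       width = 1000, agg = "mean"))
  expect_equal(unname(v3[1]), 7)
  # missing region -> fill + flag
  j <- which(gr$event_id == "ev_first")
  v4 <- trackWindowFeatures(ev, j, tr7,
                            data.frame(region = "I1", end = "first",
                                       width = 10, agg = "mean"))
  expect_equal(unname(v4), c(0, 1))
  expect_error(trackWindowFeatures(ev, i, tr7,
                                   data.frame(region = "I1", end = "first",
                                              width = 0, agg = "mean")),
               "positive")
})

test_that("k-mer and catalog counting is overlapping and window-limited", {
  k3 <- kmerCounts("AAAA", 3)
  expect_equal(unname(k3["AAA"]), 2)
  expect_equal(sum(k3), 2)
  expect_equal(catalogHits("TTGAAGAATT", "GAAGAA"), 1L)
  for (k in c(2, 3, 4)) {
    tot <- sum(kmerCounts(paste(sample(c("A", "C", "G", "T"), 10,
                                       replace = TRUE), collapse = ""), k))
    expect_equal(tot, 10 - k + 1)
  }
  expect_error(kmerCounts("ACGT", 0), "1..8")
  cats <- list(ese = "GAAGAA", ess = "TAGGGA", ise = "GGGGGG",
               iss = "CTCTCT")
  v <- kmerEseFeatures("TTGAAGAATT", NULL, "GAAGAAGAA", "CCC", cats, k = 3)
  expect_equal(unname(v["ese_a1"]), 2)       # overlapping GAAGAA at 1 and 4
  expect_equal(unname(v["miss_kmer_i2"]), 1)
})

test_that("motif and PSSM features count and normalise per region", {
  reg <- MotifRegistry(c(QKI = "ACUAAC"),
                       list(P1 = matrix(c(2, -2, -2, -2), 4, 6,
                                        dimnames = list(c("A", "C", "G", "T"),
                                                        NULL))))
  seqs <- list(I1 = "TTACTAACTT", I2 = paste(rep("A", 20), collapse = ""),
               A1 = "ACTAAC", A2 = NULL, C1 = NULL, C2 = NULL)
  v <- rbpMotifFeatures(seqs, reg)
  expect_equal(unname(v["motif_QKI_i1"]), 1)
  expect_equal(unname(v["motif_QKI_i2"]), 0)
  expect_equal(unname(v["motif_QKI_a1"]), 1)
  # poly-A I2: every 6-mer window scores 12 with the A-favouring PSSM
  sc <- pssmScan(seqs$I2, reg@pssms$P1, threshold = 0)
  expect_equal(sc$n, 15L)
  expect_equal(sc$sum, 15 * 12)
  expect_equal(unname(v["pssm_P1_i2_norm"]), 15 * 12 / 20)
  expect_error(rbpMotifFeatures(seqs, MotifRegistry()), "empty")
})

test_that("repeat counts use >= 1 bp overlap on closed intervals", {
  ev <- resolvedToyEvents()
  gr <- eventRanges(ev)
  i <- which(gr$event_id == "ev_single")    # I1 = 201..400, I2 = 501..800
  reps <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(210, 300, 790, 150),
                                                  c(240, 330, 820, 200)),
                                 family = c("Alu", "Alu", "L1", "Alu"))
  v <- repeatFeatures(ev, i, reps)
  expect_equal(unname(v["rep_alu_i1"]), 2)   # abutting repeat (150-200) excluded
  expect_equal(unname(v["rep_l1_i2"]), 1)    # straddling counts
  expect_equal(sum(repeatFeatures(ev, i, GenomicRanges::GRanges())), 0)
})

test_that("RCM seeds merge on diagonals and match a brute-force scan", {
  v <- rcmFeatures(paste(rep("G", 11), collapse = ""),
                   paste(rep("C", 11), collapse = ""))
  expect_true(v["rcm_i1_i2"] >= 1)
  # 13 nt complementary stretch -> one merged match, not 3 seeds
  set.seed(9)
  pad <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                           collapse = "")
  core <- "GATTACAGATTAC"                      # 13 nt
  i1 <- paste0(pad(20), core, pad(20))
  i2 <- paste0(pad(15), as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(core))), pad(25))
  v2 <- rcmFeatures(i1, i2, word_size = 11)
  expect_equal(unname(v2["rcm_i1_i2"]), 1)
  expect_equal(unname(v2["rcm_i1_i2_norm"]), 1 / (nchar(i1) + nchar(i2)))
  # brute-force oracle: any 11-mer of x equal to an 11-mer of revcomp(x)?
  set.seed(31)
  x <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  kx <- substring(x, 1:40, 11:50)
  krc <- substring(rc, 1:40, 11:50)
  brute_any <- any(outer(kx, krc, "=="))
  v3 <- rcmFeatures(x, x, word_size = 11)
  expect_equal(v3[["rcm_i1_i1"]] > 0, brute_any)
  expect_equal(unname(v3["rcm_i1_i1"]), 0)
  expect_error(rcmFeatures("ACGT", "ACGT", word_size = 3), ">= 4")
})

test_that("RCM counts are symmetric in the two introns", {
  set.seed(17)
  for (r in 1:5) {
    i1 <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
    i2 <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
    a <- rcmFeatures(i1, i2, word_size = 5)
    b <- rcmFeatures(i2, i1, word_size = 5)
    expect_equal(a[["rcm_i1_i2"]], b[["rcm_i1_i2"]])
  }
})

test_that("splicing amount is CPM with a positive library size", {
  expect_equal(splicingAmount(50, 1e6), 50)
  expect_equal(splicingAmount(0, 123), 0)
  expect_equal(splicingAmount(3, 2e6), 1.5)
  expect_error(splicingAmount(1, 0), "positive")
})

test_that("full cis extraction is deterministic with a stable registry", {
  gtf <- gtfPath()
  exons <- readExonsGtf(gtf)
  ev <- resolvedToyEvents(gtf)
  genome <- toyGenome()
  reg <- defaultRegistries()
  tracks <- list(conservation = ScoreTrack(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000), score = 0.5)))
  m1 <- cisFeatureMatrix(ev, genome, exons, reg$motifs, reg$catalogs,
                         reg$donor_pwm, reg$acceptor_pwm, tracks = tracks)
  m2 <- cisFeatureMatrix(ev, genome, exons, reg$motifs, reg$catalogs,
                         reg$donor_pwm, reg$acceptor_pwm, tracks = tracks)
  expect_identical(m1, m2)
  expect_false(anyNA(m1))                       # no silent missing entries
  regdf <- attr(m1, "registry")
  expect_equal(ncol(m1), nrow(regdf))
  expect_setequal(setdiff(unique(regdf$category), "splicing_amount"),
                  c("structure", "translatability", "splice_strength",
                    "conservation", "ese_ess", "kmer", "rbp_motif",
                    "repeats", "rcm"))
  expect_equal(nrow(m1), sum(eventRanges(ev)$resolved))
})
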