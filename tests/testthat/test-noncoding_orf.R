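test_that("noncoding regions are catalogued with tRNA interruptions excluded", {
  L <- 30000L
  g <- toy_genome(L)
  # two genes 427 bp apart, plus an 11,277 bp gene-free span holding one
  # 65 bp tRNA -> a long region of 11,212 noncoding bases
  tab <- annotation_table(data.frame(
    gene = c("nad4", "cox1", "trnS1", "cob"),
    type = c("CDS", "CDS", "tRNA", "CDS"),
    start = c(1000L, 3428L, 10000L, 16278L),
    end   = c(3000L, 5000L, 10064L, 18000L)),
    genome_id = "g", genome_length = L)
  nc <- noncoding_catalog(tab, g, long_threshold = 500L)
  short <- nc[nc$start == 3001L, ]
  expect_identical(short$length, 427L)
  expect_identical(short$klass, "short")
  expect_identical(short$flank_upstream, "nad4")
  expect_identical(short$flank_downstream, "cox1")
  long <- nc[nc$start == 5001L, ]
  expect_identical(c(long$end, long$length), c(16277L, 11212L))
  expect_identical(long$interrupting_features, "trnS1")
  expect_identical(long$klass, "long")
  # the span-inclusive convention is available
  nc2 <- noncoding_catalog(tab, g, exclude_trna_length = FALSE)
  expect_identical(nc2$length[nc2$start == 5001L], 11277L)
  # a fully tiled genome has no noncoding regions
  g2 <- toy_genome(300L)
  tab2 <- annotation_table(data.frame(gene = c("a", "b"), type = "CDS",
                                      start = c(1L, 151L), end = c(150L, 299L)),
                           genome_id = "g", genome_length = 300L)
  expect_identical(nrow(noncoding_catalog(tab2, g2)), 1L)  # single free base
  tab3 <- annotation_table(data.frame(gene = c("a", "b"), type = "CDS",
                                      start = c(1L, 151L), end = c(150L, 300L)),
                           genome_id = "g", genome_length = 300L)
  expect_identical(nrow(noncoding_catalog(tab3, g2)), 0L)
})

test_that("noncoding + genic + tRNA lengths sum to the genome length", {
  for (seed in c(2, 5)) {
    tr <- simulate_genome(sim_config(seed = seed))
    tab <- tr$tables$sp1
    L <- attr(tab, "genome_length")
    nc <- noncoding_catalog(tab, tr$genomes$sp1)
    len <- circular_length(tab$start, tab$end, L)
    expect_identical(sum(nc$length) + sum(len[tab$type %in% c("CDS", "rRNA")]) +
                       sum(len[tab$type == "tRNA"]), L)
  }
})

test_that("gene-length surveys recover planted per-species lengths", {
  ct <- codon_table()
  planted <- c(621L, 700L, 630L, 630L, 629L, 570L)
  panel <- withr::with_seed(1, lapply(planted, function(n) {
    aa <- substr(paste0("M", random_protein_str(n)), 1, n)
    nt <- paste0(vapply(strsplit(aa, "")[[1]], function(a) {
      codons <- names(ct$codon_to_aa)[ct$codon_to_aa == a]
      codons[1]
    }, character(1)), collapse = "")
    nt <- paste0(nt, "TAA")
    g <- genome(paste0(nt, strrep("TAGT", 25)), "g")
    tab <- annotation_table(data.frame(gene = "cox1", type = "CDS",
                                       start = 1L, end = nchar(nt)),
                            genome_id = "g", genome_length = genome_length(g))
    list(genome = g, table = tab)
  }))
  names(panel) <- paste0("sp", seq_along(panel))
  s <- survey_gene_lengths(panel, "cox1")
  expect_identical(s$n, 6L)
  expect_identical(s$min, 570L)
  expect_identical(s$max, 700L)
  expect_identical(s$mean, 630L)
  expect_identical(unname(s$lengths), planted)
  # single table -> mean equals that length
  s1 <- survey_gene_lengths(panel[2], "cox1")
  expect_identical(c(s1$n, s1$mean), c(1L, 700L))
  # a missing gene is excluded with a warning
  expect_warning(s5 <- survey_gene_lengths(
    c(panel, list(sp7 = list(genome = panel[[1]]$genome,
                             table = panel[[1]]$table[0, ]))), "cox1"),
    "missing")
  expect_identical(s5$n, 6L)
})

test_that("candidate ORFs are found inside regions and described correctly", {
  tr <- simulate_genome(sim_config(seed = 12))
  g <- tr$genomes$sp1
  tab <- tr$tables$sp1
  L <- genome_length(g)
  truth <- tr$novel_orfs$sp1
  nc <- noncoding_catalog(tab, g)
  found <- discover_candidate_orfs(g, tab, nc, min_len = 25L)
  hit <- found[found$start == truth$start, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start_codon, "TTG")
  expect_identical(hit$protein, truth$protein)
  expect_identical(hit$after_gene, "nad2")
  expect_gte(hit$n_tm_segments, 1L)
  expect_true(hit$has_signal_like_nterm)
  # every discovered ORF lies inside a scanned stop-to-stop segment
  # (extended by its terminating stop codon)
  orfs <- scan_orfs(g, codon_table(), min_len = 25L)
  for (i in seq_len(nrow(found))) {
    span <- circular_length(found$start[i], found$end[i], L)
    containing <- any(vapply(orfs, function(o) {
      seg_end <- ((o$end - 1L + 3L) %% L) + 1L
      circular_overlap(o$start, seg_end, found$start[i], found$end[i],
                       L) == span
    }, logical(1)))
    expect_true(containing)
  }
  # a region with no start codon yields nothing
  g3 <- genome(strrep("CCA", 200), "c")
  tab3 <- annotation_table(data.frame(gene = "cox1", type = "CDS",
                                      start = 1L, end = 30L),
                           genome_id = "c", genome_length = 600L)
  expect_identical(nrow(discover_candidate_orfs(
    g3, tab3, data.frame(start = 31L, end = 600L))), 0L)
})

test_that("two planted ORFs in one region are both reported after the same gene", {
  # filler is TAGT repeats: stop-dense in every frame, no initiator codons;
  # ORF interiors alternate GCT/CAC, which spells no initiator in any frame
  mk_orf <- function(n) paste0("TTG", strrep("GCTCAC", n), "TAA")
  region <- paste0(strrep("TAGT", 12), mk_orf(20), strrep("TAGT", 9),
                   mk_orf(22), strrep("TAGT", 12))
  g <- genome(paste0(strrep("TAGT", 100), region, strrep("TAGT", 26)), "p")
  L <- genome_length(g)
  tab <- annotation_table(data.frame(
    gene = c("nad5", "nad6"), type = "CDS",
    start = c(297L, 801L), end = c(400L, 860L)),
    genome_id = "p", genome_length = L)
  found <- discover_candidate_orfs(
    g, tab, data.frame(start = 401L, end = 400L + nchar(region)),
    min_len = 25L)
  expect_identical(nrow(found), 2L)
  expect_identical(unique(found$after_gene), "nad5")
  expect_identical(found$length_aa, c(41L, 45L))
  expect_identical(found$start, c(449L, 611L))
})

test_that("hydropathy segments match the all-windows oracle", {
  # 19 consecutive Ile in a poly-Gly context
  p <- paste0(strrep("G", 30), strrep("I", 19), strrep("G", 30))
  tm <- hydropathy_tm(p)
  expect_identical(nrow(tm), 1L)
  expect_lte(tm$start_aa, 40L); expect_gte(tm$end_aa, 40L)
  # the window centered on the Ile run averages the full 4.5
  expect_gte(tm$mean_hydropathy, 1.6)
  # all-Arg protein has none
  expect_identical(nrow(hydropathy_tm(strrep("R", 40))), 0L)
  # too-short protein warns and returns empty
  expect_warning(empty <- hydropathy_tm("MKL"), "shorter")
  expect_identical(nrow(empty), 0L)
  # oracle equivalence on random proteins
  withr::with_seed(31, {
    for (i in 1:100) {
      p <- random_protein_str(sample(19:120, 1))
      expect_equal(hydropathy_tm(p), oracle_hydropathy_tm(p),
                   ignore_attr = TRUE)
    }
  })
})

test_that("the signal-like N-terminus rule follows its definition", {
  expect_true(signal_like_nterm(paste0("MKR", strrep("L", 10), "DDDDD")))
  # acidic N-terminus: no K/R in the first five residues
  expect_false(signal_like_nterm(paste0("MDDDD", strrep("L", 10), "DDD")))
  # hydrophobic core starting at residue 40 is outside the 1-30 window
  expect_false(signal_like_nterm(paste0("MK", strrep("D", 38),
                                        strrep("L", 10), "DD")))
  expect_error(signal_like_nterm("MKLLL"), "15")
})
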