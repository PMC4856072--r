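test_that("local alignment scores identical and unrelated sequences correctly", {
  # sum of BLOSUM62 diagonals for M,N,S,W = 5+6+4+11
  expect_identical(local_align("MNSW", "MNSW")$score, 26)
  # all-negative substitution scores give the empty zero-score alignment
  res <- local_align("AAAA", "WWWW")
  expect_identical(res$score, 0)
  expect_identical(res$a_aligned, "")
  # residues outside the matrix alphabet are scored as X
  expect_identical(local_align("MUUU", "MUUU")$score,
                   local_align("MXXX", "MXXX")$score)
  expect_error(local_align("", "MNSW"), "non-empty")
})

test_that("local alignment score equals the exhaustive DP oracle on random pairs", {
  mat <- blosum62x()
  withr::with_seed(13, {
    for (i in 1:200) {
      a <- random_protein_str(sample(5:30, 1))
      b <- random_protein_str(sample(5:30, 1))
      expect_identical(local_align(a, b)$score,
                       oracle_local_score(a, b, mat))
    }
  })
})

test_that("homology grouping recovers simulated orthologs and ignores species order", {
  cfg <- sim_config(seed = 4, substitution_rate = 0.3)
  tr <- simulate_panel(cfg)
  ct <- codon_table()
  orf_sets <- lapply(tr$genomes, scan_orfs, table = ct)
  reference <- annotation_proteins(tr$genomes$sp1, tr$tables$sp1, ct)
  groups <- group_homologs(orf_sets, reference)
  expect_length(groups, 12L)
  expect_true(all(vapply(groups, function(g) length(g$members), integer(1)) == 4L))
  # each member's ORF covers the gene's annotated locus
  for (g in groups) {
    for (sp in names(g$members)) {
      tab <- tr$tables[[sp]]
      feat <- tab[tab$gene == g$gene, ]
      L <- attr(tab, "genome_length")
      expect_gt(circular_overlap(g$members[[sp]]$start, g$members[[sp]]$end,
                                 feat$start, feat$end, L), 0L)
    }
  }
  # permutation invariance in species order
  groups_rev <- group_homologs(rev(orf_sets), reference)
  for (g in names(groups)) {
    expect_mapequal(
      lapply(groups[[g]]$members, `[[`, "start"),
      lapply(groups_rev[[g]]$members, `[[`, "start"))
  }
  # a species lacking the gene leaves a 3-member group with recorded absence
  g3 <- group_homologs(orf_sets[1:3], reference)
  expect_true(all(vapply(g3, function(g) length(g$members), integer(1)) == 3L))
  # decoy ORFs with no reference resemblance join no group
  decoy <- list(d = list(fake_orf(strrep("W", 90), 1L, 1L, "ATG")))
  gd <- group_homologs(decoy, reference)
  expect_true(all(vapply(gd, function(g) length(g$members), integer(1)) == 0L))
})

test_that("center-star alignment handles identical members and end extensions", {
  core <- "MSTWKLDEQNRHPAGVFYCI"
  g <- fake_group("toy", list(
    a = fake_orf(core, 1L, 1L, "ATG"),
    b = fake_orf(core, 1L, 1L, "ATG")))
  g <- multi_align(g)
  expect_identical(unname(g$alignment[["a"]]), core)
  expect_true(all(g$column_occupancy == 1))

  ext <- paste0(strrep("Q", 10), core)
  g2 <- fake_group("toy", list(
    a = fake_orf(ext, 1L, 1L, "ATG"),
    b = fake_orf(core, 1L, 1L, "ATG"),
    c = fake_orf(core, 1L, 1L, "ATG"),
    d = fake_orf(core, 1L, 1L, "ATG")))
  g2 <- multi_align(g2)
  expect_identical(nchar(g2$alignment[["a"]]), 30L)
  expect_identical(unname(g2$column_occupancy[1:10]), rep(0.25, 10))
  expect_identical(unname(g2$column_occupancy[11:30]), rep(1, 20))
  expect_true(all(g2$column_occupancy %in% c(0.25, 0.5, 0.75, 1)))
})

test_that("start selection maximizes conserved coverage, then codon preference", {
  core <- "MSTWKLDEQNRHPAGVFYCIMSTWKLDEQNRHPAGVFYCI"  # 40 aa, shared
  junk <- strrep("Q", 10)
  L <- 10000L
  # member a carries a 10-codon private extension whose columns are sparse;
  # its candidates: TTG at the first conserved column (codon 11) and ATG 20
  # codons downstream
  orf_a <- fake_orf(paste0(junk, core), start = 301L,
                    candidate_idx = c(11L, 31L),
                    candidate_codons = c("TTG", "ATG"))
  grp <- fake_group("toy", list(
    a = orf_a,
    b = fake_orf(core, 601L, 1L, "TTG"),
    c = fake_orf(core, 501L, 1L, "TTG"),
    d = fake_orf(core, 401L, 1L, "TTG")))
  grp <- multi_align(grp)
  tabs <- lapply(stats::setNames(nm = c("a", "b", "c", "d")), function(sp)
    annotation_table(data.frame(gene = c("prev", "toy"), type = "CDS",
                                start = c(1L, 301L), end = c(200L, 500L)),
                     genome_id = sp, genome_length = L))
  calls <- select_start(grp, tabs)
  a <- calls[calls$species == "a", ]
  expect_identical(a$codon, "TTG")
  expect_identical(a$position, orf_a$candidate_starts$position[1])
  expect_identical(a$conserved_columns_covered, 40L)

  # tie-break: an ATG at the same first conserved column beats the TTG
  # sitting in the sparse private extension
  orf_a2 <- fake_orf(paste0(junk, core), start = 301L,
                     candidate_idx = c(5L, 11L),
                     candidate_codons = c("TTG", "ATG"))
  grp2 <- fake_group("toy", list(
    a = orf_a2,
    b = fake_orf(core, 601L, 1L, "TTG"),
    c = fake_orf(core, 501L, 1L, "TTG"),
    d = fake_orf(core, 401L, 1L, "TTG")))
  grp2 <- multi_align(grp2)
  a2 <- select_start(grp2, tabs)
  a2 <- a2[a2$species == "a", ]
  expect_identical(a2$codon, "ATG")
})

test_that("the overlap penalty rejects an upstream ATG running into the previous gene", {
  core <- "MSTWKLDEQNRHPAGVFYCIMSTWKLDEQNRHPAGVFYCI"
  L <- 10000L
  # candidates with equal conserved coverage (both at or before the first
  # conserved column): ATG overlapping the upstream gene by 30 bp vs TTG
  # with zero overlap 10 codons downstream
  orf_a <- fake_orf(paste0(strrep("Q", 10), core), start = 271L,
                    candidate_idx = c(1L, 11L),
                    candidate_codons = c("ATG", "TTG"))
  grp <- fake_group("toy", list(
    a = orf_a,
    b = fake_orf(core, 601L, 1L, "TTG"),
    c = fake_orf(core, 501L, 1L, "TTG"),
    d = fake_orf(core, 401L, 1L, "TTG")))
  grp <- multi_align(grp)
  tabs <- lapply(stats::setNames(nm = c("a", "b", "c", "d")), function(sp)
    annotation_table(data.frame(gene = c("prev", "toy"), type = "CDS",
                                start = c(1L, 301L), end = c(300L, 500L)),
                     genome_id = sp, genome_length = L))
  calls <- select_start(grp, tabs)
  a <- calls[calls$species == "a", ]
  expect_identical(a$codon, "TTG")
  expect_identical(a$upstream_gap, 0L)
})
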