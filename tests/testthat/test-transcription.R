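toy_cov_table <- function(L = 2000L) {
  annotation_table(data.frame(
    gene = c("cox1", "rrnL"),
    type = c("CDS", "rRNA"),
    start = c(101L, 1001L), end = c(700L, 1600L)),
    genome_id = "g", genome_length = L)
}

test_that("strand_fraction tests single-strand transcription and masks rRNA", {
  L <- 2000L
  tab <- toy_cov_table(L)
  sense <- rep(10, L)
  expect_identical(strand_fraction(coverage_track("g", sense), tab), 1)
  # antisense confined to the rRNA locus: excluded -> 1, included -> < 1
  anti <- numeric(L); anti[1001:1600] <- 5
  tr <- coverage_track("g", sense, anti)
  expect_identical(strand_fraction(tr, tab, exclude_rrna = TRUE), 1)
  expect_lt(strand_fraction(tr, tab, exclude_rrna = FALSE), 1)
  # zero coverage is undefined, not 0 or 1
  expect_true(is.na(strand_fraction(coverage_track("g", numeric(L)), tab)))
})

test_that("region calling applies floor, merge and thresholds as stated", {
  L <- 5000L
  tab <- toy_cov_table(L)
  # planted 1000 bp intergenic block at depth 200 on zero background
  sense <- numeric(L); sense[2001:3000] <- 200
  reg <- call_transcribed_regions(coverage_track("g", sense), tab,
                                  min_len = 100L, min_mean_depth = 50)
  expect_identical(nrow(reg), 1L)
  expect_identical(c(reg$start, reg$end), c(2001L, 3000L))
  expect_identical(reg$label, "intergenic")
  expect_identical(reg$mean_depth, 200)
  # 90 bp region is below the length floor
  sense2 <- numeric(L); sense2[2001:2090] <- 200
  expect_identical(nrow(call_transcribed_regions(coverage_track("g", sense2),
                                                 tab, 100L, 50)), 0L)
  # two segments separated by 30 bp merge into one region
  sense3 <- numeric(L); sense3[2001:2300] <- 200; sense3[2331:2600] <- 200
  reg3 <- call_transcribed_regions(coverage_track("g", sense3), tab, 100L, 50)
  expect_identical(nrow(reg3), 1L)
  expect_identical(c(reg3$start, reg3$end), c(2001L, 2600L))
  # a region over the CDS is labelled genic-overlap
  sense4 <- numeric(L); sense4[101:700] <- 200
  expect_identical(call_transcribed_regions(coverage_track("g", sense4),
                                            tab, 100L, 50)$label, "genic-overlap")
  # wrap across the origin
  sense5 <- numeric(L); sense5[c(4801:5000, 1:100)] <- 80
  reg5 <- call_transcribed_regions(coverage_track("g", sense5), tab, 100L, 50)
  expect_identical(c(reg5$start, reg5$end, reg5$length), c(4801L, 100L, 300L))
})

test_that("every emitted region satisfies its own thresholds (self-consistency)", {
  cfg <- sim_config(seed = 6)
  tr <- simulate_genome(cfg)
  cov <- simulate_coverage(tr)
  L <- cfg$genome_length
  reg <- call_transcribed_regions(cov, tr$tables$sp1, min_len = 100L,
                                  min_mean_depth = 10, floor = 8)
  expect_gt(nrow(reg), 0L)
  for (i in seq_len(nrow(reg))) {
    pos <- circular_positions(reg$start[i], reg$end[i], L)
    expect_identical(length(pos), reg$length[i])
    expect_gte(reg$length[i], 100L)
    expect_gte(reg$mean_depth[i], 10)
    expect_identical(mean(cov$sense[pos]), reg$mean_depth[i])
  }
})

test_that("deeper tracks never lose called bases (plateau-style monotonicity)", {
  cfg <- sim_config(seed = 16)
  tr <- simulate_genome(cfg)
  a <- simulate_coverage(tr)
  b <- simulate_coverage(simulate_genome(sim_config(seed = 17)))
  stopifnot(length(a$sense) == length(b$sense))
  ab <- coverage_track("g", a$sense + b$sense, a$antisense + b$antisense)
  covered <- function(track) {
    r <- call_transcribed_regions(track, tr$tables$sp1, 100L,
                                  min_mean_depth = 10, floor = 8)
    sum(r$length)
  }
  expect_gte(covered(ab), covered(a))
})

test_that("drop-off detection localizes steps with the closed-form score", {
  L <- 3000L
  v <- rep(1000, L); v[1501:3000] <- 10
  v[1:150] <- 10  # make the wrap boundary quiet
  v[1:150] <- 10; v[2851:3000] <- 10
  tr <- coverage_track("g", v)
  d <- detect_dropoffs(tr, window = 50L, min_log2 = 2, min_separation = 100L)
  down <- d[d$direction == "down", ]
  expect_identical(down$position, 1500L)
  expect_equal(down$log2_ratio, log2(1001 / 11), tolerance = 1e-12)
  expect_true(all(c(150L) %in% d$position[d$direction == "up"]))
  # flat track: nothing
  expect_identical(nrow(detect_dropoffs(coverage_track("g", rep(7, L)))), 0L)
  # rising step is reported as "up" (symmetry)
  v2 <- rep(10, L); v2[1501:2500] <- 1000
  d2 <- detect_dropoffs(coverage_track("g", v2))
  expect_identical(d2$direction[d2$position == 1500L], "up")
  expect_identical(d2$direction[d2$position == 2500L], "down")
})

test_that("drop-off calls are stable under x10 depth scaling", {
  cfg <- sim_config(seed = 9)
  tr <- simulate_genome(cfg)
  cov <- simulate_coverage(tr)
  L <- cfg$genome_length
  d1 <- detect_dropoffs(cov)
  d10 <- detect_dropoffs(coverage_track("g", cov$sense * 10,
                                        cov$antisense * 10))
  # scaling only sharpens contrasts: every site survives within a few bases
  # (the pseudocount shifts weak boundaries by a base or two)
  for (i in seq_len(nrow(d1))) {
    same <- d10[d10$direction == d1$direction[i], ]
    expect_lte(min(circular_distance(d1$position[i], same$position, L)), 5L)
  }
})

test_that("start calls match planted up-steps within tolerance", {
  calls <- data.frame(species = "s", gene = c("a", "b"),
                      position = c(5000L, 6000L), codon = "TTG")
  sites <- data.frame(position = c(5003L, 6050L),
                      log2_ratio = c(-3, -3), direction = "up")
  out <- annotate_starts_with_dropoffs(calls, sites, genome_length = 10000L,
                                       tolerance = 10L)
  expect_identical(out$matched_position, c(5003L, NA_integer_))
})

test_that("coverage TSV and bedGraph readers agree with the in-memory track", {
  g <- toy_genome(400L)
  withr::with_seed(3, {
    sense <- rpois(400, 5); anti <- rpois(400, 1)
  })
  tr <- coverage_track(g$id, sense, anti)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_tsv(tr, f)
  tr2 <- read_coverage_tsv(f, g)
  expect_identical(tr2$sense, as.numeric(sense))
  expect_identical(tr2$antisense, as.numeric(anti))

  fs <- withr::local_tempfile(fileext = ".bedGraph")
  fa <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("g\t0\t100\t5", "g\t100\t400\t2"), fs)
  writeLines("g\t350\t400\t1", fa)
  tr3 <- read_bedgraph_pair(fs, fa, g)
  expect_identical(tr3$sense, c(rep(5, 100), rep(2, 300)))
  expect_identical(sum(tr3$antisense), 50)
  tr4 <- read_bedgraph_pair(fs, NULL, g)
  expect_identical(sum(tr4$antisense), 0)
})
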