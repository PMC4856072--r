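# Synthetic circular mitochondrial genomes, ortholog panels and stranded
# coverage tracks with planted ground truth, so every pipeline stage can be
# exercised and measured without external data.

.sim_protein_lengths <- c(
  cox1 = 630L, cox2 = 220L, cox3 = 230L, cob = 330L, nad1 = 270L,
  nad2 = 300L, nad3 = 115L, nad4 = 400L, nad4L = 95L, nad5 = 460L,
  nad6 = 160L, atp6 = 210L)

.sim_rrna_lengths <- c(rrnL = 900L, rrnS = 650L)

# template gene order; <NCR> marks the long noncoding region (hosting the
# planted lncRNAs and trnS1) and <NOVEL> the 321 bp gap after nad2 hosting
# the planted novel ORF. cob-nad4L-nad4 form the conserved cartridge.
.sim_template <- c(
  "cox1", "trnN", "cox2", "trnI", "cox3", "trnT", "nad6", "trnY", "nad5",
  "trnK", "trnW", "<NCR>", "trnA", "cob", "nad4L", "nad4", "trnF", "atp6",
  "trnG", "nad2", "<NOVEL>", "trnV", "nad3", "trnQ", "trnM", "nad1",
  "trnP", "trnR", "rrnL", "trnC", "rrnS", "trnL1", "trnL2", "trnS2",
  "trnD", "trnE", "trnH")

.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a ~20 kb circular
#' genome carrying 12 protein-coding genes, 2 rRNAs and 22 tRNAs all on one
#' strand; short intergenic gaps; an extended noncoding region interrupted
#' by a single tRNA and hosting planted transcribed intergenic regions
#' (1000 bp at 2000x, 710 bp at 15x and 1100 bp at 250x); a 321 bp gap
#' after nad2 hosting a planted 60-codon ORF with a transmembrane/signal
#' architecture; a start-codon mix dominated by the noncanonical TTG;
#' per-transcription-unit coverage plateaus with sharp boundaries over a
#' near-zero background; and low-rate antisense noise confined to rRNA
#' loci.
#'
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the seed.
#' @param genome_length Circular genome length (default 20000).
#' @param gap_range Min/max intergenic gap length in bases (default 60-80;
#'   every gap upstream of a CDS ends with an in-frame TAA, so planted
#'   reading frames open exactly at the planted start codon).
#' @param start_codon_mix Named probabilities over ATG/GTG/TTG
#'   (default TTG 0.5, ATG 0.4, GTG 0.1).
#' @param protein_lengths Named amino-acid lengths of the 12 proteins.
#' @param planted_lncrnas List of `c(length, depth)` pairs planted in the
#'   long noncoding region.
#' @param plant_novel_orf Plant the unannotated 60-codon ORF after nad2.
#' @param novel_orf_depth Coverage plateau of the novel transcript
#'   (default 600).
#' @param dropoff_at_boundaries Sharp coverage steps at transcription-unit
#'   boundaries; `FALSE` smooths them over ~50 bp.
#' @param background_depth Mean depth outside transcription units
#'   (default 1).
#' @param antisense_rrna_rate Antisense depth inside rRNA loci as a
#'   fraction of sense depth (default 0.02; 0 gives a perfectly
#'   single-stranded track).
#' @param unit_depth_range Min/max of the log-uniform per-unit plateau
#'   depth (default 10-2000).
#' @param n_species Panel size for [simulate_panel()] (default 4).
#' @param substitution_rate Per-residue amino-acid substitution probability
#'   for non-reference species (default 0.2).
#' @param trna_relocations Number of tRNAs relocated to a different
#'   major-gene interval in each non-reference species (default 1).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 20000L,
                       gap_range = c(60L, 80L),
                       start_codon_mix = c(TTG = 0.5, ATG = 0.4, GTG = 0.1),
                       protein_lengths = .sim_protein_lengths,
                       planted_lncrnas = list(c(1000L, 2000), c(710L, 15),
                                              c(1100L, 250)),
                       plant_novel_orf = TRUE,
                       novel_orf_depth = 600,
                       dropoff_at_boundaries = TRUE,
                       background_depth = 1,
                       antisense_rrna_rate = 0.02,
                       unit_depth_range = c(10, 2000),
                       n_species = 4L,
                       substitution_rate = 0.2,
                       trna_relocations = 1L) {
  stopifnot(abs(sum(start_codon_mix) - 1) < 1e-9,
            all(names(start_codon_mix) %in% c("ATG", "GTG", "TTG")),
            length(gap_range) == 2L, gap_range[1] >= 10L,
            all(protein_lengths >= 80L),
            substitution_rate >= 0, substitution_rate < 1)
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 gap_range = as.integer(gap_range),
                 start_codon_mix = start_codon_mix,
                 protein_lengths = protein_lengths,
                 planted_lncrnas = planted_lncrnas,
                 plant_novel_orf = isTRUE(plant_novel_orf),
                 novel_orf_depth = novel_orf_depth,
                 dropoff_at_boundaries = isTRUE(dropoff_at_boundaries),
                 background_depth = background_depth,
                 antisense_rrna_rate = antisense_rrna_rate,
                 unit_depth_range = unit_depth_range,
                 n_species = as.integer(n_species),
                 substitution_rate = substitution_rate,
                 trna_relocations = as.integer(trna_relocations)),
            class = "sim_config")
}

.random_nt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform synonymous back-translation; stop-free interiors by construction
.back_translate <- function(protein, ct, start_codon = NULL) {
  aa2codon <- split(names(ct$codon_to_aa), ct$codon_to_aa)
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(a) {
    ch <- aa2codon[[a]]
    ch[sample.int(length(ch), 1L)]
  }, character(1))
  if (!is.null(start_codon)) codons[1] <- start_codon
  paste(codons, collapse = "")
}

.random_protein <- function(n) paste(c("M", sample(.aa20, n - 1L, replace = TRUE)),
                                     collapse = "")

# the planted novel ORF protein: positively charged + hydrophobic
# N-terminus (signal-like) and a 21-residue transmembrane core
.novel_orf_protein <- function() {
  paste(c("M", "K", "R", rep("L", 8),
          strsplit("QNSTDEQN", "")[[1]],
          rep(c("I", "L", "V"), 7),
          strsplit("SKQDNTEYHQNSDE", "")[[1]],
          rep("S", 60 - 3 - 8 - 8 - 21 - 14)), collapse = "")
}

# interval identity (label of the nearest preceding CDS/rRNA item,
# circularly) for every slot of a template; used to constrain tRNA
# relocation targets
.template_intervals <- function(template, major_labels) {
  is_major <- template %in% major_labels
  iv <- character(length(template))
  cur <- template[max(which(is_major))]  # wrap: slots before the first major
  for (i in seq_along(template)) {
    if (is_major[i]) cur <- template[i]
    iv[i] <- cur
  }
  iv
}

# relocate k tRNAs to slots in a different major-gene interval
.relocate_trnas <- function(template, k, major_labels) {
  if (k == 0L) return(list(template = template, moved = character(0)))
  movable <- template[grepl("^trn", template) & template != "trnS1"]
  moved <- sample(movable, k)
  for (t in moved) {
    iv <- .template_intervals(template, major_labels)
    src <- iv[match(t, template)]
    template <- template[template != t]
    iv <- .template_intervals(template, major_labels)
    # insert after a slot whose interval differs from the source interval;
    # never split the cob-nad4L-nad4 cartridge, and keep clear of the
    # NCR/NOVEL markers
    ok <- which(iv != src &
                  !template %in% c("<NCR>", "<NOVEL>", "cob", "nad4L"))
    at <- ok[sample.int(length(ok), 1L)]
    template <- append(template, t, after = at)
  }
  list(template = template, moved = sort(moved))
}

# Build one species' genome, annotation, truth and transcription units
# using the current RNG stream.
.build_species <- function(cfg, ct, template, proteins, start_codons, species) {
  L <- cfg$genome_length
  lnc_lens <- vapply(cfg$planted_lncrnas, `[`, numeric(1), 1L)
  lnc_depths <- vapply(cfg$planted_lncrnas, `[`, numeric(1), 2L)
  trna_labels <- template[grepl("^trn", template)]
  trna_len <- stats::setNames(sample(60:70, length(trna_labels) + 1L,
                                     replace = TRUE),
                              c(trna_labels, "trnS1"))
  gaps <- stats::setNames(
    sample(seq.int(cfg$gap_range[1], cfg$gap_range[2]),
           length(template), replace = TRUE), template)
  feat_len <- function(item) {
    if (item %in% names(cfg$protein_lengths))
      return(3L * cfg$protein_lengths[[item]] + 3L)
    if (item %in% names(.sim_rrna_lengths)) return(.sim_rrna_lengths[[item]])
    trna_len[[item]]
  }
  novel_len <- if (cfg$plant_novel_orf) 321L else 0L
  fixed <- sum(vapply(setdiff(template, c("<NCR>", "<NOVEL>")), feat_len,
                      integer(1))) +
    sum(gaps[!template %in% c("<NCR>", "<NOVEL>")]) + novel_len
  spacer <- 130L
  ncr_len <- L - fixed
  ncr_min <- sum(lnc_lens) + trna_len[["trnS1"]] +
    (length(lnc_lens) + 2L) * spacer
  if (ncr_len < ncr_min)
    stop("infeasible packing: genome_length too small by ",
         ncr_min - ncr_len, " bp")

  pieces <- character(0)
  pos <- 1L
  feats <- list(); units <- list(); truth_starts <- list()
  lnc_truth <- list(); novel_truth <- NULL
  add_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add_feature <- function(gene, type, len, start_codon = NA_character_) {
    feats[[length(feats) + 1L]] <<- data.frame(
      gene = gene, type = type, start = pos, end = pos + len - 1L,
      start_codon = start_codon)
  }
  add_gap <- function(n, stop_before_cds = FALSE) {
    if (n <= 0L) return(invisible())
    g <- .random_nt(n)
    if (stop_before_cds && n >= 3L)
      g <- paste0(substr(g, 1L, n - 3L), "TAA")
    add_piece(g)
  }
  for (item in template) {
    if (item == "<NCR>") {
      # spacer, lnc1, spacer, lnc2, spacer, trnS1, spacer, lnc3, spacer(+rest)
      rest <- ncr_len - sum(lnc_lens) - trna_len[["trnS1"]] -
        (length(lnc_lens) + 2L) * spacer
      trns1_before <- min(3L, length(lnc_lens) + 1L)
      add_trns1 <- function() {
        add_feature("trnS1", "tRNA", trna_len[["trnS1"]])
        add_piece(.random_nt(trna_len[["trnS1"]]))
        add_gap(spacer)
      }
      add_gap(spacer)
      if (trns1_before > length(lnc_lens)) add_trns1()
      for (i in seq_along(lnc_lens)) {
        if (i == trns1_before) add_trns1()
        lnc_truth[[i]] <- data.frame(start = pos,
                                     end = pos + lnc_lens[i] - 1L,
                                     depth = lnc_depths[i])
        units[[length(units) + 1L]] <- data.frame(
          start = pos, end = pos + lnc_lens[i] - 1L,
          kind = "lncRNA", depth = lnc_depths[i])
        add_piece(.random_nt(lnc_lens[i]))
        add_gap(spacer)
      }
      add_gap(rest)
    } else if (item == "<NOVEL>") {
      if (cfg$plant_novel_orf) {
        # the in-frame TAA at the gap end makes the planted TTG the most
        # upstream start owning the novel ORF's stop
        add_gap(120L, stop_before_cds = TRUE)
        prot <- .novel_orf_protein()
        nt <- paste0(.back_translate(prot, ct, start_codon = "TTG"), "TAA")
        novel_truth <- data.frame(start = pos, end = pos + nchar(nt) - 1L,
                                  protein = prot, start_codon = "TTG")
        units[[length(units) + 1L]] <- data.frame(
          start = pos, end = pos + nchar(nt) - 1L,
          kind = "novel_orf", depth = cfg$novel_orf_depth)
        add_piece(nt)
        add_gap(321L - 120L - nchar(nt))
      }
    } else if (item %in% names(cfg$protein_lengths)) {
      add_gap(gaps[[item]], stop_before_cds = TRUE)
      prot <- proteins[[item]]
      nt <- paste0(.back_translate(prot, ct, start_codon = start_codons[[item]]),
                   sample(ct$stops, 1L))
      truth_starts[[item]] <- data.frame(species = species, gene = item,
                                         position = pos,
                                         codon = start_codons[[item]])
      add_feature(item, "CDS", nchar(nt), start_codon = start_codons[[item]])
      add_piece(nt)
    } else if (item %in% names(.sim_rrna_lengths)) {
      add_gap(gaps[[item]])
      add_feature(item, "rRNA", .sim_rrna_lengths[[item]])
      add_piece(.random_nt(.sim_rrna_lengths[[item]]))
    } else {  # tRNA
      add_gap(gaps[[item]])
      add_feature(item, "tRNA", trna_len[[item]])
      add_piece(.random_nt(trna_len[[item]]))
    }
  }
  seq <- paste(pieces, collapse = "")
  stopifnot(nchar(seq) == L)

  # merge the cartridge (cob-nad4L-nad4) into one transcription unit and
  # give every other CDS/rRNA its own
  ftab <- do.call(rbind, feats)
  cart <- c("cob", "nad4L", "nad4")
  for (g in setdiff(ftab$gene[ftab$type %in% c("CDS", "rRNA")], cart)) {
    row <- ftab[ftab$gene == g, ]
    units[[length(units) + 1L]] <- data.frame(start = row$start, end = row$end,
                                              kind = row$type, depth = NA_real_)
  }
  units[[length(units) + 1L]] <- data.frame(
    start = ftab$start[ftab$gene == "cob"],
    end = ftab$end[ftab$gene == "nad4"],
    kind = "cartridge", depth = NA_real_)

  # rotate the whole circle so features wrap the origin in general position
  offset <- sample(0:(L - 1L), 1L)
  rot <- function(p) ((p + offset - 1L) %% L) + 1L
  if (offset > 0L)
    seq <- paste0(substr(seq, L - offset + 1L, L), substr(seq, 1L, L - offset))
  ftab$start <- rot(ftab$start); ftab$end <- rot(ftab$end)
  units <- do.call(rbind, units)
  units$start <- rot(units$start); units$end <- rot(units$end)
  starts <- do.call(rbind, truth_starts)
  starts$position <- rot(starts$position)
  lnc <- do.call(rbind, lnc_truth)
  if (is.null(lnc))
    lnc <- data.frame(start = integer(0), end = integer(0), depth = numeric(0))
  lnc$start <- rot(lnc$start); lnc$end <- rot(lnc$end)
  if (!is.null(novel_truth)) {
    novel_truth$start <- rot(novel_truth$start)
    novel_truth$end <- rot(novel_truth$end)
  }
  g <- genome(seq, id = species, species = species)
  tab <- annotation_table(ftab, genome_id = species, genome_length = L)
  rownames(units) <- rownames(starts) <- rownames(lnc) <- NULL
  list(genome = g, table = tab, units = units, true_starts = starts,
       true_lncrnas = lnc, novel_orf = novel_truth)
}

#' Simulate a single circular mitochondrial genome with planted truth
#'
#' Genes are in-frame ORFs whose interiors are stop-free by construction
#' (random proteins back-translated with uniform synonymous codons under
#' the flatworm code), each opened by a start codon drawn from
#' `start_codon_mix` and closed by a stop; the preceding intergenic gap
#' ends with an in-frame TAA, so the stop-to-stop segment opens exactly at
#' the planted start. The cob-nad4L-nad4 cartridge is always contiguous.
#' The whole circle is randomly rotated, so features wrap the origin in
#' general position. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param codon_table A [codon_table()].
#' @return Object of class `synthetic_truth`: named lists `genomes`,
#'   `tables`, `units` (transcription units for [simulate_coverage()]),
#'   plus `true_starts`, `true_lncrnas`, `novel_orfs`, `relocated_trnas`
#'   and `config`.
#' @export
simulate_genome <- function(config, codon_table = mitocurate::codon_table()) {
  set.seed(config$seed)
  proteins <- lapply(config$protein_lengths, .random_protein)
  start_codons <- lapply(
    config$protein_lengths,
    function(...) sample(names(config$start_codon_mix), 1L,
                         prob = config$start_codon_mix))
  sp <- "sp1"
  b <- .build_species(config, codon_table, .sim_template, proteins,
                      start_codons, sp)
  structure(list(genomes = stats::setNames(list(b$genome), sp),
                 tables = stats::setNames(list(b$table), sp),
                 units = stats::setNames(list(b$units), sp),
                 true_starts = b$true_starts,
                 true_lncrnas = stats::setNames(list(b$true_lncrnas), sp),
                 novel_orfs = stats::setNames(list(b$novel_orf), sp),
                 relocated_trnas = stats::setNames(list(character(0)), sp),
                 config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d species, %d bp genome, seed %d\n",
              length(x$genomes), x$config$genome_length, x$config$seed))
  invisible(x)
}

#' Simulate a species panel with shared planted starts
#'
#' Species 2..n derive from species 1 by amino-acid substitutions at
#' `substitution_rate` per residue (initiator Met fixed; synonymous
#' back-translation is redrawn per species), preserving the planted start
#' codons, with `trna_relocations` tRNAs moved to a different major-gene
#' interval per species. Intergenic sequence, gap lengths and tRNA lengths
#' are redrawn per species so only the genes are homologous.
#'
#' @inheritParams simulate_genome
#' @return A `synthetic_truth` over `config$n_species` species.
#' @export
simulate_panel <- function(config, codon_table = mitocurate::codon_table()) {
  stopifnot(config$n_species >= 2L)
  set.seed(config$seed)
  proteins <- lapply(config$protein_lengths, .random_protein)
  start_codons <- lapply(
    config$protein_lengths,
    function(...) sample(names(config$start_codon_mix), 1L,
                         prob = config$start_codon_mix))
  major_labels <- c(names(config$protein_lengths), names(.sim_rrna_lengths))
  species <- paste0("sp", seq_len(config$n_species))
  out <- list()
  for (s in seq_along(species)) {
    if (s == 1L) {
      prot_s <- proteins
      template <- .sim_template
      moved <- character(0)
    } else {
      prot_s <- lapply(proteins, .mutate_protein, rate = config$substitution_rate)
      rel <- .relocate_trnas(.sim_template, config$trna_relocations,
                             major_labels)
      template <- rel$template
      moved <- rel$moved
    }
    b <- .build_species(config, codon_table, template, prot_s, start_codons,
                        species[s])
    b$moved <- moved
    out[[species[s]]] <- b
  }
  structure(list(
    genomes = lapply(out, `[[`, "genome"),
    tables = lapply(out, `[[`, "table"),
    units = lapply(out, `[[`, "units"),
    true_starts = do.call(rbind, c(lapply(out, `[[`, "true_starts"),
                                   make.row.names = FALSE)),
    true_lncrnas = lapply(out, `[[`, "true_lncrnas"),
    novel_orfs = lapply(out, `[[`, "novel_orf"),
    relocated_trnas = lapply(out, `[[`, "moved"),
    config = config), class = "synthetic_truth")
}

.mutate_protein <- function(protein, rate) {
  res <- strsplit(protein, "")[[1]]
  hit <- which(stats::runif(length(res)) < rate)
  hit <- hit[hit > 1L]  # the initiator Met is fixed
  for (i in hit) res[i] <- sample(setdiff(.aa20, res[i]), 1L)
  paste(res, collapse = "")
}

#' Simulate a stranded coverage track for one simulated species
#'
#' Each transcription unit (every CDS and rRNA, the cob-nad4L-nad4
#' cartridge as a single unit, the planted lncRNAs and the novel ORF) gets
#' a depth plateau - log-uniform over `unit_depth_range` for genes, the
#' planted depth for lncRNAs/novel ORF - over the configured background,
#' with per-base Poisson noise. tRNAs stay at background (polyA-selected
#' libraries deplete them). Antisense depth is Poisson at
#' `antisense_rrna_rate` times the sense mean inside rRNA loci and zero
#' elsewhere. Deterministic given the config seed and species.
#'
#' @param truth A `synthetic_truth`.
#' @param config Its [sim_config()] (defaults to `truth$config`).
#' @param species Which species' track to simulate (default first).
#' @return A [coverage_track()] with attributes `true_dropoffs`
#'   (data.frame `position`, `direction` of every planted sharp boundary;
#'   `position` p is the boundary between p and p+1) and `unit_depths`.
#' @export
simulate_coverage <- function(truth, config = truth$config,
                              species = names(truth$genomes)[1]) {
  set.seed((config$seed + 104729L * match(species, names(truth$genomes))) %%
             .Machine$integer.max)
  L <- config$genome_length
  units <- truth$units[[species]]
  draw <- is.na(units$depth)
  lo <- log(config$unit_depth_range[1]); hi <- log(config$unit_depth_range[2])
  units$depth[draw] <- exp(stats::runif(sum(draw), lo, hi))
  mu <- rep(config$background_depth, L)
  for (i in seq_len(nrow(units)))
    mu[circular_positions(units$start[i], units$end[i], L)] <- units$depth[i]
  dropoffs <- NULL
  if (config$dropoff_at_boundaries) {
    up <- data.frame(position = ((units$start - 2L) %% L) + 1L,
                     direction = "up", stringsAsFactors = FALSE)
    dn <- data.frame(position = units$end, direction = "down",
                     stringsAsFactors = FALSE)
    contrast <- abs(log2((units$depth + 1) / (config$background_depth + 1)))
    dropoffs <- rbind(up[contrast >= 2, ], dn[contrast >= 2, ])
    dropoffs <- dropoffs[order(dropoffs$position), ]
    rownames(dropoffs) <- NULL
  } else {
    # smooth unit edges over ~50 bp so boundaries are not sharp
    k <- rep(1 / 51, 51)
    mu <- as.numeric(stats::filter(mu, k, sides = 2, circular = TRUE))
  }
  sense <- stats::rpois(L, mu)
  anti_mu <- numeric(L)
  tab <- truth$tables[[species]]
  rr <- tab[tab$type == "rRNA", , drop = FALSE]
  for (i in seq_len(nrow(rr))) {
    p <- circular_positions(rr$start[i], rr$end[i], L)
    anti_mu[p] <- config$antisense_rrna_rate * mu[p]
  }
  antisense <- stats::rpois(L, anti_mu)
  tr <- coverage_track(truth$genomes[[species]]$id, sense, antisense)
  attr(tr, "true_dropoffs") <- dropoffs
  attr(tr, "unit_depths") <- units
  tr
}
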