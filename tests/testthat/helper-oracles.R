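# Independent oracles: small, slow, written directly from first principles
# so they share no code path with the implementation they check.

# Affine-gap Smith-Waterman by full dynamic programming. A gap of length k
# costs open + k * ext (the same convention as the implementation's
# alignment backend). Returns the optimal local score only.
oracle_local_score <- function(a, b, mat, open = 11, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # ends with x_i over a gap
  F <- matrix(NEG, n + 1, m + 1)  # ends with y_j over a gap
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i - 1, j] - (open + ext), E[i - 1, j] - ext)
    F[i, j] <- max(H[i, j - 1] - (open + ext), F[i, j - 1] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[x[i - 1], y[j - 1]],
                   E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

# Stop-to-stop ORF enumeration on a circular genome whose length is a
# multiple of 3, by walking each frame as a closed ring of codons (no
# genome doubling). Returns data.frame(start, length_aa), sorted.
oracle_scan_orfs <- function(seq, ct, min_len = 80L) {
  L <- nchar(seq)
  stopifnot(L %% 3L == 0L)
  out <- list()
  for (f in 0:2) {
    n <- L %/% 3L
    pos <- ((f + 3L * (seq_len(n) - 1L)) %% L) + 1L  # codon start positions
    codons <- vapply(pos, function(p) {
      idx <- ((p - 1L + 0:2) %% L) + 1L
      paste(substring(seq, idx, idx), collapse = "")
    }, character(1))
    stops <- which(codons %in% ct$stops)
    if (length(stops) == 0L) {
      if (n >= min_len)
        out[[length(out) + 1L]] <- data.frame(start = pos[1], length_aa = n)
      next
    }
    for (k in seq_along(stops)) {
      cur <- stops[k]
      nxt <- if (k == length(stops)) stops[1] + n else stops[k + 1]
      len <- nxt - cur - 1L
      if (len >= min_len)
        out[[length(out) + 1L]] <- data.frame(
          start = pos[((cur) %% n) + 1L], length_aa = len)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(data.frame(start = integer(0), length_aa = integer(0)))
  out <- unique(out)
  out[order(out$start, out$length_aa), , drop = FALSE]
}

# Exhaustive minimal tRNA deletion set over ALL subsets, with rotation
# equality checked by explicitly trying every rotation offset.
oracle_rotation_equal <- function(x, y) {
  if (length(x) != length(y)) return(FALSE)
  if (length(x) == 0L) return(TRUE)
  for (r in seq_along(y)) {
    if (all(x == c(y[r:length(y)], y[seq_len(r - 1L)])[seq_along(x)]))
      return(TRUE)
  }
  FALSE
}

oracle_trna_difference <- function(a, b, max_k = 4L) {
  la <- a$order$label; lb <- b$order$label
  trnas <- union(la[a$order$class == "tRNA"], lb[b$order$class == "tRNA"])
  for (k in 0:max_k) {
    if (k > length(trnas)) break
    sets <- if (k == 0L) list(character(0)) else
      asplit(utils::combn(trnas, k), 2L)
    for (S in sets) {
      xa <- la[!la %in% S]; xb <- lb[!lb %in% S]
      if (oracle_rotation_equal(xa, xb)) return(k)
    }
  }
  max_k + 1L
}

# All-windows hydropathy segments, written directly from the definition
# (decimal hydropathies summed exactly as integers x10).
oracle_hydropathy_tm <- function(protein, window = 19L, threshold = 1.6) {
  kd <- kyte_doolittle()
  v <- kd[strsplit(protein, "")[[1]]]
  v[is.na(v)] <- 0
  v10 <- as.integer(round(10 * v))
  n <- length(v)
  h <- (window - 1L) %/% 2L
  centers <- seq.int(h + 1L, n - h)
  sc10 <- vapply(centers, function(c) sum(v10[(c - h):(c + h)]), integer(1))
  sc <- sc10 / (10 * window)
  ok <- sc10 >= 10 * threshold * window - 1e-9
  segs <- list()
  i <- 1L
  while (i <= length(ok)) {
    if (ok[i]) {
      j <- i
      while (j < length(ok) && ok[j + 1L]) j <- j + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        start_aa = centers[i], end_aa = centers[j],
        mean_hydropathy = mean(sc[i:j]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(segs) == 0L)
    return(data.frame(start_aa = integer(0), end_aa = integer(0),
                      mean_hydropathy = numeric(0)))
  do.call(rbind, segs)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

random_protein_str <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# fraction of true boundaries recovered within +/- tol by same-direction
# detected sites
dropoff_recovery <- function(found, truth, L, tol = 10L) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    same <- found[found$direction == truth$direction[i], , drop = FALSE]
    nrow(same) > 0L &&
      min(circular_distance(truth$position[i], same$position, L)) <= tol
  }, logical(1))
  mean(hit)
}

# best reciprocal overlap of each truth interval with called regions
region_recovery <- function(regions, truth, L) {
  vapply(seq_len(nrow(truth)), function(i) {
    tl <- circular_length(truth$start[i], truth$end[i], L)
    if (nrow(regions) == 0L) return(0)
    ov <- vapply(seq_len(nrow(regions)), function(j)
      circular_overlap(regions$start[j], regions$end[j],
                       truth$start[i], truth$end[i], L), integer(1))
    j <- which.max(ov)
    min(ov[j] / regions$length[j], ov[j] / tl)
  }, numeric(1))
}

# start-call accuracy against a truth table
start_accuracy <- function(calls, truth) {
  m <- merge(calls, truth, by = c("species", "gene"), suffixes = c("", ".true"))
  mean(m$position == m$position.true & m$codon == m$codon.true)
}
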