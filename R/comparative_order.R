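# Circular gene-order comparison: canonical rotations, the minimal tRNA
# deletion-set distance, and conserved gene blocks (e.g. the
# cytb-nad4L-nad4 cartridge).

#' Construct a circular gene order
#'
#' Duplicate labels get positional suffixes (`trnN`, `trnN-2`, ...). The
#' order is rotated so the anchor gene comes first; this canonical rotation
#' makes equal circular orders identical vectors.
#'
#' @param labels Gene labels, 5' to 3' around the circle.
#' @param classes `"major"` or `"tRNA"` per label.
#' @param species Species label.
#' @param anchor Gene used for rotation (default `"cox1"`).
#' @return Object of class `gene_order`: list with `order` (data.frame
#'   `label`, `class`), `species`, `anchor`.
#' @export
gene_order <- function(labels, classes, species = "", anchor = "cox1") {
  stopifnot(length(labels) == length(classes),
            all(classes %in% c("major", "tRNA")))
  if (!any(classes == "major")) stop("a gene order needs at least one major gene")
  dup <- ave(seq_along(labels), labels, FUN = seq_along)
  labels <- ifelse(dup > 1L, paste0(labels, "-", dup), labels)
  i <- match(anchor, labels)
  if (is.na(i)) stop("anchor gene '", anchor, "' absent from order")
  rot <- c(seq.int(i, length(labels)), seq_len(i - 1L))
  structure(list(order = data.frame(label = labels[rot], class = classes[rot]),
                 species = species, anchor = anchor),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s: %d genes (%d tRNA), anchored at %s\n",
              x$species, nrow(x$order), sum(x$order$class == "tRNA"), x$anchor))
  cat(" ", paste(x$order$label, collapse = " "), "\n")
  invisible(x)
}

#' Gene order of an annotation table
#'
#' Features are taken in canonical circular position (wrap-around features
#' placed by their start); ncRNA and ORF features are excluded; tRNAs are
#' distinguished from "major" genes (CDS and rRNA).
#'
#' @param table A `mito_annotation`.
#' @param species Species label (defaults to the table's genome id).
#' @param anchor Rotation anchor (default `"cox1"`).
#' @return A [gene_order()].
#' @export
order_from_annotations <- function(table, species = attr(table, "genome_id"),
                                   anchor = "cox1") {
  keep <- table[!table$type %in% c("ncRNA", "ORF"), , drop = FALSE]
  keep <- keep[order(keep$start), , drop = FALSE]
  gene_order(keep$gene,
             ifelse(keep$type == "tRNA", "tRNA", "major"),
             species = species, anchor = anchor)
}

# are two label vectors equal up to rotation?
.is_rotation <- function(x, y) {
  if (length(x) != length(y)) return(FALSE)
  if (length(x) == 0L) return(TRUE)
  sep <- "\r"
  pat <- paste0(sep, paste(x, collapse = sep), sep)
  hay <- paste0(sep, paste(c(y, y), collapse = sep), sep)
  grepl(pat, hay, fixed = TRUE)
}

#' Minimal tRNA deletion-set distance between two circular gene orders
#'
#' The tRNA difference between two genomes is the size of the smallest set
#' of tRNA labels whose deletion from both circular orders makes them
#' identical up to rotation. tRNAs present in only one order are forced
#' into the set; the remaining subsets are searched exhaustively up to
#' `max_k`. When no set of size `<= max_k` exists the difference is
#' reported as the lower bound `max_k + 1` with `resolved = FALSE`.
#'
#' @param a,b `gene_order` objects over the same major genes.
#' @param max_k Largest deletion set searched exhaustively (default 4).
#' @return Object of class `order_comparison`: `species_pair`,
#'   `trna_difference`, `relocated_trnas`, `major_gene_identical`,
#'   `resolved`.
#' @export
trna_difference <- function(a, b, max_k = 4L) {
  la <- a$order$label; lb <- b$order$label
  ta <- la[a$order$class == "tRNA"]; tb <- lb[b$order$class == "tRNA"]
  ma <- la[a$order$class == "major"]; mb <- lb[b$order$class == "major"]
  major_identical <- .is_rotation(ma, mb)
  forced <- c(setdiff(ta, tb), setdiff(tb, ta))
  shared <- intersect(ta, tb)
  result <- function(k, S, resolved) {
    structure(list(species_pair = c(a$species, b$species),
                   trna_difference = k,
                   relocated_trnas = sort(S),
                   major_gene_identical = major_identical,
                   resolved = resolved),
              class = "order_comparison")
  }
  if (!major_identical || length(forced) > max_k)
    return(result(max_k + 1L, character(0), FALSE))
  strip <- function(lab, S) lab[!lab %in% S]
  for (k in seq.int(length(forced), max_k)) {
    extra <- k - length(forced)
    combos <- if (extra == 0L) list(character(0))
      else if (extra > length(shared)) list()
      else asplit(utils::combn(shared, extra), 2L)
    for (add in combos) {
      S <- c(forced, as.character(add))
      if (.is_rotation(strip(la, S), strip(lb, S))) return(result(k, S, TRUE))
    }
  }
  result(max_k + 1L, character(0), FALSE)
}

#' @export
print.order_comparison <- function(x, ...) {
  cat(sprintf("<order_comparison> %s vs %s: tRNA difference %d%s%s\n",
              x$species_pair[1], x$species_pair[2], x$trna_difference,
              if (!x$resolved) " (unresolved lower bound)" else "",
              if (!x$major_gene_identical) " [major gene orders differ]" else ""))
  if (length(x$relocated_trnas))
    cat("  relocated:", paste(x$relocated_trnas, collapse = ", "), "\n")
  invisible(x)
}

#' Gene blocks conserved across all orders
#'
#' Maximal runs of labels that are contiguous, in the same order, in every
#' input order (circular adjacency runs), of length at least `min_block`.
#' If the whole circle is conserved, the full order is returned as one
#' block.
#'
#' @param orders List of at least two `gene_order` objects over the same
#'   labels.
#' @param min_block Minimum run length (default 2).
#' @return List of character vectors (label runs).
#' @export
conserved_blocks <- function(orders, min_block = 2L) {
  stopifnot(length(orders) >= 2L)
  labs <- orders[[1]]$order$label
  succ_of <- function(o) {
    l <- o$order$label
    stats::setNames(c(l[-1], l[1]), l)
  }
  succs <- lapply(orders, succ_of)
  common <- vapply(labs, function(g) {
    s <- vapply(succs, function(sc) if (g %in% names(sc)) sc[[g]] else NA_character_,
                character(1))
    if (anyNA(s) || length(unique(s)) != 1L) NA_character_ else s[1]
  }, character(1))
  common <- common[!is.na(common)]
  if (length(common) == length(labs)) return(list(labs))  # fully conserved circle
  # chain maximal runs: start genes are those that are nobody's successor
  starts <- setdiff(names(common), unname(common))
  blocks <- lapply(starts, function(g) {
    run <- g
    while (g %in% names(common)) {
      g <- common[[g]]
      run <- c(run, g)
    }
    run
  })
  blocks[vapply(blocks, length, integer(1)) >= min_block]
}

#' Pairwise gene-order comparison over a panel
#'
#' @param orders Named list of `gene_order` objects.
#' @param max_k Passed to [trna_difference()].
#' @return `data.frame` with one row per species pair.
#' @export
compare_orders <- function(orders, max_k = 4L) {
  nm <- names(orders)
  out <- list()
  for (i in seq_len(length(orders) - 1L)) for (j in seq.int(i + 1L, length(orders))) {
    cmp <- trna_difference(orders[[i]], orders[[j]], max_k = max_k)
    out[[length(out) + 1L]] <- data.frame(
      species_a = nm[i], species_b = nm[j],
      trna_difference = cmp$trna_difference,
      relocated = paste(cmp$relocated_trnas, collapse = ","),
      major_gene_identical = cmp$major_gene_identical,
      resolved = cmp$resolved)
  }
  do.call(rbind, out)
}
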