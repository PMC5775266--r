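ORIENTATION_CATEGORIES <- c("CIS_AS_5PRIME", "CUTORNA", "CIS_AS_OTHER",
                            "AMBIGUOUS", "SENSE_OVERLAP", "NONE")

#' Classifier parameters
#'
#' Geometry windows used to classify a gene--sRNA pair. "Neighboring" means
#' overlap or a gap of at most `adjacency_window` nucleotides. The 5' window
#' spans the ribosome binding site and start codon
#' (`five_prime_upstream` nt upstream of the start through
#' `five_prime_downstream` nt into the coding sequence, strand-aware); an
#' antisense transcript intersecting it can block translation initiation.
#' The 3' window covers the gene terminus (`three_prime_inside` nt inside
#' the gene through `three_prime_downstream` nt past its end), where
#' convergent overlapping transcripts (cutoRNAs) act.
#'
#' @param adjacency_window Maximum gap in nt for two features to count as
#'   neighbors (default 100).
#' @param five_prime_upstream Nt upstream of the start codon in the 5'
#'   window (default 15, a typical RBS offset).
#' @param five_prime_downstream Nt into the CDS in the 5' window (default 3,
#'   the start codon).
#' @param three_prime_inside Nt of the gene 3' terminus inside the 3'
#'   window (default 50).
#' @param three_prime_downstream Nt past the gene end in the 3' window
#'   (default 50).
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(adjacency_window = 100,
                              five_prime_upstream = 15,
                              five_prime_downstream = 3,
                              three_prime_inside = 50,
                              three_prime_downstream = 50) {
  p <- list(adjacency_window = as.integer(adjacency_window),
            five_prime_upstream = as.integer(five_prime_upstream),
            five_prime_downstream = as.integer(five_prime_downstream),
            three_prime_inside = as.integer(three_prime_inside),
            three_prime_downstream = as.integer(three_prime_downstream))
  if (any(vapply(p, function(x) is.na(x) || x < 0L, TRUE))) {
    stop("all classifier window parameters must be >= 0", call. = FALSE)
  }
  structure(p, class = "classifier_params")
}

## 5' window of a gene as (start, end) in genome coordinates, strand-aware.
five_prime_window <- function(gstart, gend, gstrand, params) {
  if (gstrand == "+") {
    c(gstart - params$five_prime_upstream,
      gstart + params$five_prime_downstream)
  } else {
    c(gend - params$five_prime_downstream,
      gend + params$five_prime_upstream)
  }
}

three_prime_window <- function(gstart, gend, gstrand, params) {
  if (gstrand == "+") {
    c(gend - params$three_prime_inside,
      gend + params$three_prime_downstream)
  } else {
    c(gstart - params$three_prime_downstream,
      gstart + params$three_prime_inside)
  }
}

intervals_intersect <- function(a, b) a[1L] <= b[2L] && b[1L] <= a[2L]

## Scalar classification core on plain coordinates; every public entry
## point funnels through here.
classify_core <- function(same_chrom, gs, ge, gstrand, ss, se, sstrand,
                          params) {
  if (!gstrand %in% c("+", "-")) {
    stop("invalid input: gene strand must be '+' or '-'", call. = FALSE)
  }
  if (gs > ge || ss > se || gs < 1L || ss < 1L) {
    stop("invalid input: intervals need 1 <= start <= end", call. = FALSE)
  }
  ov <- if (same_chrom) max(0L, min(ge, se) - max(gs, ss) + 1L) else 0L
  gap <- if (!same_chrom) NA_integer_
         else if (ov > 0L) 0L
         else max(0L, max(gs, ss) - min(ge, se) - 1L)
  category <- "NONE"
  if (same_chrom && (ov > 0L || gap <= params$adjacency_window)) {
    if (sstrand == "*") {
      category <- "AMBIGUOUS"
    } else if (sstrand != gstrand) {
      w5 <- five_prime_window(gs, ge, gstrand, params)
      w3 <- three_prime_window(gs, ge, gstrand, params)
      on_3prime_side <- if (gstrand == "+") ss > ge else se < gs
      category <- if (intervals_intersect(c(ss, se), w5)) {
        "CIS_AS_5PRIME"
      } else if (intervals_intersect(c(ss, se), w3) ||
                 (ov == 0L && on_3prime_side)) {
        "CUTORNA"
      } else {
        "CIS_AS_OTHER"
      }
    } else if (ov > 0L) {
      category <- "SENSE_OVERLAP"
    }
  }
  list(category = category, overlap_nt = ov, gap_nt = gap)
}

pair_arrows <- function(gs, ge, gstrand, ss, se, sstrand) {
  gene_tok <- arrow_token(gstrand, "gene")
  srna_tok <- arrow_token(sstrand, "srna")
  if (ss > gs || (ss == gs && se >= ge)) {
    paste(gene_tok, srna_tok)
  } else {
    paste(srna_tok, gene_tok)
  }
}

#' Classify the orientation of one gene--sRNA pair
#'
#' Assigns one of six relationship categories to a (gene, small RNA) pair
#' by strand and interval geometry, in this precedence order:
#'
#' 1. `AMBIGUOUS` -- the sRNA strand is unknown and the pair neighbors
#'    (overlap, or gap at most `adjacency_window`);
#' 2. `CIS_AS_5PRIME` -- antisense (opposite strand) and the sRNA intersects
#'    the gene's 5' window (RBS + start codon);
#' 3. `CUTORNA` -- antisense and the sRNA intersects the 3' window, or is a
#'    non-overlapping neighbor lying on the gene's 3' side;
#' 4. `CIS_AS_OTHER` -- any other antisense neighbor (overlap touching
#'    neither window, or a 5'-side gap beyond the 5' window);
#' 5. `SENSE_OVERLAP` -- same strand with overlap;
#' 6. `NONE` -- otherwise (including different chromosomes).
#'
#' A 5'-window hit takes precedence over a 3'-window hit (an sRNA spanning
#' the whole gene is `CIS_AS_5PRIME`): probing and primer design target
#' translation-initiation regions, so 5' evidence dominates.
#'
#' @param gene Length-1 `GRanges` with `gene_id` metadata; strand `+`/`-`.
#' @param srna Length-1 `GRanges` with `srna_id` metadata; strand may be `*`.
#' @param params A [classifier_params()] object.
#' @return A one-row data.frame: `gene_id`, `srna_id`, `category`,
#'   `overlap_nt`, `gap_nt`, `arrows` (gene and sRNA tokens in genomic
#'   order).
#' @examples
#' g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 2000), "+")
#' S4Vectors::mcols(g)$gene_id <- "SCOT001"
#' s <- GenomicRanges::GRanges("chrT", IRanges::IRanges(950, 1060), "-")
#' S4Vectors::mcols(s)$srna_id <- "scrT001"
#' classify_pair(g, s, classifier_params())
#' @export
classify_pair <- function(gene, srna, params = classifier_params()) {
  stopifnot(length(gene) == 1L, length(srna) == 1L)
  classify_pairs(gene, srna, params)
}

#' Classify parallel vectors of gene--sRNA pairs
#'
#' Vectorized form of [classify_pair()]: element i of `genes` is classified
#' against element i of `srnas` (lengths must match, or one side have
#' length 1).
#'
#' @param genes,srnas `GRanges` of equal length (or length 1).
#' @param params A [classifier_params()] object.
#' @return A data.frame with one row per pair, columns as in
#'   [classify_pair()].
#' @export
classify_pairs <- function(genes, srnas, params = classifier_params()) {
  n <- max(length(genes), length(srnas))
  if (length(genes) == 1L) genes <- rep(genes, n)
  if (length(srnas) == 1L) srnas <- rep(srnas, n)
  stopifnot(length(genes) == n, length(srnas) == n)
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  schrom <- as.character(GenomicRanges::seqnames(srnas))
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  ss <- GenomicRanges::start(srnas); se <- GenomicRanges::end(srnas)
  gstrand <- as.character(GenomicRanges::strand(genes))
  sstrand <- as.character(GenomicRanges::strand(srnas))
  gene_id <- S4Vectors::mcols(genes)$gene_id
  srna_id <- S4Vectors::mcols(srnas)$srna_id
  cat <- character(n); ov <- integer(n); gap <- integer(n)
  arrows <- character(n)
  for (i in seq_len(n)) {
    core <- classify_core(gchrom[i] == schrom[i], gs[i], ge[i], gstrand[i],
                          ss[i], se[i], sstrand[i], params)
    cat[i] <- core$category
    ov[i] <- core$overlap_nt
    gap[i] <- core$gap_nt
    arrows[i] <- pair_arrows(gs[i], ge[i], gstrand[i], ss[i], se[i],
                             sstrand[i])
  }
  data.frame(gene_id = gene_id, srna_id = srna_id, category = cat,
             overlap_nt = ov, gap_nt = gap, arrows = arrows,
             stringsAsFactors = FALSE)
}

#' Classify every neighboring gene--sRNA pair in a catalog
#'
#' Emits one call for every (gene, sRNA) pair whose category is not `NONE`.
#' With `best_only = TRUE`, each sRNA is reduced to its single best gene
#' partner, ties broken by smaller gap, then larger overlap, then
#' lexicographically smaller `gene_id`.
#'
#' @param genes `GRanges` from [read_gene_annotation()].
#' @param srnas `GRanges` from [read_srna_catalog()].
#' @param params A [classifier_params()] object.
#' @param best_only Keep only the best gene partner per sRNA?
#' @return A data.frame of calls (columns as in [classify_pair()], plus
#'   `source` when present in `srnas`), ordered by (gene_id, srna_id).
#' @export
classify_catalog <- function(genes, srnas, params = classifier_params(),
                             best_only = FALSE) {
  empty <- data.frame(gene_id = character(), srna_id = character(),
                      category = character(), overlap_nt = integer(),
                      gap_nt = integer(), arrows = character(),
                      stringsAsFactors = FALSE)
  if (length(genes) == 0L || length(srnas) == 0L) return(empty)
  ## candidate pairs within the adjacency window (strand-blind)
  hits <- GenomicRanges::findOverlaps(srnas, genes,
                                      maxgap = params$adjacency_window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  calls <- classify_pairs(genes[S4Vectors::subjectHits(hits)],
                          srnas[S4Vectors::queryHits(hits)], params)
  calls <- calls[calls$category != "NONE", , drop = FALSE]
  if (nrow(calls) == 0L) return(empty)
  if ("source" %in% names(S4Vectors::mcols(srnas))) {
    calls$source <- S4Vectors::mcols(srnas)$source[
      match(calls$srna_id, S4Vectors::mcols(srnas)$srna_id)]
  }
  if (best_only) {
    calls <- calls[order(calls$srna_id, calls$gap_nt, -calls$overlap_nt,
                         calls$gene_id, method = "radix"), , drop = FALSE]
    calls <- calls[!duplicated(calls$srna_id), , drop = FALSE]
  }
  calls <- calls[order(calls$gene_id, calls$srna_id, method = "radix"), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls
}

arrow_token <- function(strand, type = c("gene", "srna")) {
  type <- match.arg(type)
  if (type == "gene") {
    switch(strand, "+" = "->", "-" = "<-",
           stop("gene strand must be '+' or '-'", call. = FALSE))
  } else {
    switch(strand, "+" = "=>", "-" = "<=", "*" = "*",
           stop("unknown sRNA strand symbol '", strand, "'", call. = FALSE))
  }
}

#' Render the arrow notation of a locus
#'
#' Compact strand notation for a small RNA and its flanking genes, ordered
#' left to right along the genome: genes render `->` (plus) or `<-` (minus);
#' the sRNA renders `=>` (plus), `<=` (minus) or `*` (unknown strand).
#'
#' @param left,right Length-1 `GRanges` (or `NULL` if absent flank).
#' @param srna Length-1 `GRanges`; strand may be `*`.
#' @return A single string, tokens joined by single spaces.
#' @examples
#' # a minus-strand asRNA between a plus- and a minus-strand gene
#' g1 <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 10), "+")
#' s  <- GenomicRanges::GRanges("c", IRanges::IRanges(12, 20), "-")
#' g2 <- GenomicRanges::GRanges("c", IRanges::IRanges(22, 30), "-")
#' render_arrows(g1, s, g2)  # "-> <= <-"
#' @export
render_arrows <- function(left = NULL, srna, right = NULL) {
  tokens <- c(
    if (!is.null(left))
      arrow_token(as.character(GenomicRanges::strand(left)), "gene"),
    arrow_token(as.character(GenomicRanges::strand(srna)), "srna"),
    if (!is.null(right))
      arrow_token(as.character(GenomicRanges::strand(right)), "gene"))
  paste(tokens, collapse = " ")
}
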