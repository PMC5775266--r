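suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

mk_gene <- function(chrom, start, end, strand, id = "g1", product = "") {
  g <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(g)$gene_id <- id
  mcols(g)$product <- product
  g
}

mk_srna <- function(chrom, start, end, strand, id = "s1",
                    source = "testcat") {
  s <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(s)$srna_id <- id
  mcols(s)$source <- source
  mcols(s)$status <- "predicted"
  s
}

## Independent brute-force orientation oracle. Works on explicit position
## sets (seq/intersect/setdiff), never on interval arithmetic, so it shares
## no code path with classify_pair().
oracle_classify <- function(gchrom, gs, ge, gstrand,
                            schrom, ss, se, sstrand,
                            p = classifier_params()) {
  if (gchrom != schrom) return("NONE")
  gpos <- seq(gs, ge)
  spos <- seq(ss, se)
  ov <- length(intersect(gpos, spos))
  gap <- if (ov > 0) {
    0L
  } else {
    lo <- min(max(gpos), max(spos))
    hi <- max(min(gpos), min(spos))
    length(setdiff(seq(lo, hi), c(lo, hi)))  # positions strictly between
  }
  if (ov == 0 && gap > p$adjacency_window) return("NONE")
  if (sstrand == "*") return("AMBIGUOUS")
  if (sstrand == gstrand) {
    return(if (ov > 0) "SENSE_OVERLAP" else "NONE")
  }
  if (gstrand == "+") {
    w5 <- seq(gs - p$five_prime_upstream, gs + p$five_prime_downstream)
    w3 <- seq(ge - p$three_prime_inside, ge + p$three_prime_downstream)
    beyond3 <- all(spos > max(gpos))
  } else {
    w5 <- seq(ge - p$five_prime_downstream, ge + p$five_prime_upstream)
    w3 <- seq(gs - p$three_prime_downstream, gs + p$three_prime_inside)
    beyond3 <- all(spos < min(gpos))
  }
  if (length(intersect(spos, w5)) > 0) return("CIS_AS_5PRIME")
  if (length(intersect(spos, w3)) > 0 || (ov == 0 && beyond3)) {
    return("CUTORNA")
  }
  "CIS_AS_OTHER"
}

## Random toy geometries on a chromosome of at most `chrlen` nt. Gene
## coordinates keep enough flank that the strand-aware windows stay
## meaningful on a short contig.
random_geometry <- function(n, chrlen = 300L, seed = 1L) {
  set.seed(seed)
  gs <- sample(60:(chrlen - 120), n, replace = TRUE)
  ss <- sample(1:(chrlen - 30), n, replace = TRUE)
  data.frame(
    gs = gs,
    ge = gs + sample(20:100, n, replace = TRUE),
    gstrand = sample(c("+", "-"), n, replace = TRUE),
    ss = ss,
    se = ss + sample(5:60, n, replace = TRUE),
    sstrand = sample(c("+", "-", "*"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

classify_geometry <- function(geo, i, p = classifier_params()) {
  classify_pair(mk_gene("c", geo$gs[i], geo$ge[i], geo$gstrand[i]),
                mk_srna("c", geo$ss[i], geo$se[i], geo$sstrand[i]),
                p)$category
}

## classify a whole geometry table at once (one GRanges build per side)
batch_classify <- function(geo, p = classifier_params()) {
  genes <- GRanges("c", IRanges(geo$gs, geo$ge), strand = geo$gstrand)
  mcols(genes)$gene_id <- sprintf("g%05d", seq_len(nrow(geo)))
  srnas <- GRanges("c", IRanges(geo$ss, geo$se), strand = geo$sstrand)
  mcols(srnas)$srna_id <- sprintf("s%05d", seq_len(nrow(geo)))
  classify_pairs(genes, srnas, p)
}

oracle_classify_all <- function(geo, p = classifier_params()) {
  vapply(seq_len(nrow(geo)), function(i)
    oracle_classify("c", geo$gs[i], geo$ge[i], geo$gstrand[i],
                    "c", geo$ss[i], geo$se[i], geo$sstrand[i], p), "")
}

## mirror a geometry row: reverse-complement the whole locus
flip_geometry <- function(geo, L = 1000L) {
  flip <- function(x) ifelse(x == "+", "-", ifelse(x == "-", "+", "*"))
  data.frame(
    gs = L + 1L - geo$ge, ge = L + 1L - geo$gs, gstrand = flip(geo$gstrand),
    ss = L + 1L - geo$se, se = L + 1L - geo$ss, sstrand = flip(geo$sstrand),
    stringsAsFactors = FALSE
  )
}

write_tsv <- function(d, path = tempfile(fileext = ".tsv")) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## in-memory evidence builder mirroring read_expression_tables() output
make_evidence <- function(gene_id, folds, bard = NULL) {
  data.frame(
    gene_id = gene_id,
    bard_ratio = if (is.null(bard)) rep(NA_real_, length(gene_id)) else bard,
    fold_changes = I(folds),
    stringsAsFactors = FALSE
  )
}
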