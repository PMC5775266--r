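## Seeded fixture generators. All randomness is confined to with_seed() so
## generation never disturbs (and is never disturbed by) the caller's RNG.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, gc = 0.72) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## sRNA geometry per category, as offsets relative to the gene start of a
## plus-strand gene (start_offset, end_offset, strand relative to the gene:
## "opp", "same", "unk"). Margins are generous (tens of nt from every
## window boundary) so planted categories are recovered exactly under the
## default classifier windows.
locus_geometry <- function(gene_len, srna_len) {
  g1 <- gene_len - 1L
  list(
    CIS_AS_5PRIME = list(a = -40L, b = -40L + srna_len - 1L, rel = "opp"),
    CUTORNA       = list(a = g1 - 40L, b = g1 - 40L + srna_len - 1L,
                         rel = "opp"),
    CIS_AS_OTHER  = list(a = 100L, b = 100L + srna_len - 1L, rel = "opp"),
    AMBIGUOUS     = list(a = 150L, b = 150L + srna_len - 1L, rel = "unk"),
    SENSE_OVERLAP = list(a = 100L, b = 100L + srna_len - 1L, rel = "same"),
    NONE          = list(a = g1 + 150L, b = g1 + 150L + srna_len - 1L,
                         rel = "opp")
  )
}

#' Generate a toy genome with planted antisense loci of every category
#'
#' Builds a single synthetic chromosome carrying `n_per_category`
#' independent loci for each of the six orientation categories. Each locus
#' is a gene (random strand) plus one sRNA placed with the geometry that
#' defines its category under `params`; loci are separated by several times
#' the adjacency window so they cannot cross-talk. The base composition is
#' GC-rich (72% by default, Streptomyces-like). Ground truth carries the
#' planted category per locus and planted evidence-filter membership per
#' gene (genes of antisense categories are marked selected: 5'-overlap and
#' ambiguous loci by fold change, cutoRNA loci by both fold change and
#' RNase III binding, other-overlap loci by binding only).
#'
#' @param seed Integer seed; output is byte-identical per seed.
#' @param n_per_category Loci per category (default 3).
#' @param params A [classifier_params()] object.
#' @param gene_len,srna_len Feature lengths in nt (defaults 400, 100).
#' @param gc GC content of the random background (default 0.72).
#' @return List with `genome` (named `DNAStringSet`), `genes` and `srnas`
#'   (`GRanges` as produced by the annotation readers) and `truth`
#'   (data.frame: `locus`, `gene_id`, `srna_id`, `category`,
#'   `selected_fold`, `selected_bard`).
#' @examples
#' ls <- generate_locus_set(seed = 7, n_per_category = 1)
#' classify_catalog(ls$genes, ls$srnas)
#' @export
generate_locus_set <- function(seed, n_per_category = 3,
                               params = classifier_params(),
                               gene_len = 400L, srna_len = 100L,
                               gc = 0.72) {
  stopifnot(n_per_category >= 0)
  geom <- locus_geometry(gene_len, srna_len)
  categories <- names(geom)
  spacing <- max(500L, 5L * params$adjacency_window)
  with_seed(seed, {
    cursor <- 300L
    rows <- list()
    for (cat in categories) {
      for (k in seq_len(n_per_category)) {
        g <- geom[[cat]]
        if (g$a < -cursor + 1L) {
          stop("generation error: locus geometry extends past contig start",
               call. = FALSE)
        }
        gstrand <- sample(c("+", "-"), 1L)
        g0 <- cursor
        g1 <- g0 + gene_len - 1L
        if (gstrand == "+") {
          ss <- g0 + g$a; se <- g0 + g$b
        } else {  # mirror the layout about the gene
          ss <- g1 - g$b; se <- g1 - g$a
        }
        sstrand <- switch(g$rel,
                          unk = "*",
                          same = gstrand,
                          opp = if (gstrand == "+") "-" else "+")
        i <- length(rows) + 1L
        rows[[i]] <- data.frame(
          locus = i,
          gene_id = sprintf("SYNG%03d", i),
          srna_id = sprintf("syns%03d", i),
          category = cat,
          gene_start = g0, gene_end = g1, gene_strand = gstrand,
          srna_start = ss, srna_end = se, srna_strand = sstrand,
          selected_fold = cat %in% c("CIS_AS_5PRIME", "CUTORNA",
                                     "AMBIGUOUS"),
          selected_bard = cat %in% c("CUTORNA", "CIS_AS_OTHER"),
          stringsAsFactors = FALSE)
        cursor <- max(g1, se) + spacing
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(locus = integer(), gene_id = character(),
                 srna_id = character(), category = character(),
                 gene_start = integer(), gene_end = integer(),
                 gene_strand = character(), srna_start = integer(),
                 srna_end = integer(), srna_strand = character(),
                 selected_fold = logical(), selected_bard = logical(),
                 stringsAsFactors = FALSE)
    chrlen <- if (nrow(truth))
      max(truth$gene_end, truth$srna_end) + 300L else 1000L
    genome <- Biostrings::DNAStringSet(random_dna(chrlen, gc))
    names(genome) <- "chrS"

    genes <- GenomicRanges::GRanges(
      rep("chrS", nrow(truth)),
      IRanges::IRanges(truth$gene_start, truth$gene_end),
      strand = truth$gene_strand)
    S4Vectors::mcols(genes)$gene_id <- truth$gene_id
    S4Vectors::mcols(genes)$product <-
      sprintf("synthetic locus, %s", truth$category)
    genes <- sort_by_position(genes, "gene_id")

    srnas <- GenomicRanges::GRanges(
      rep("chrS", nrow(truth)),
      IRanges::IRanges(truth$srna_start, truth$srna_end),
      strand = truth$srna_strand)
    S4Vectors::mcols(srnas)$srna_id <- truth$srna_id
    S4Vectors::mcols(srnas)$source <- rep("synthetic", nrow(truth))
    S4Vectors::mcols(srnas)$status <- rep("predicted", nrow(truth))
    srnas <- sort_by_position(srnas, "srna_id")

    list(genome = genome, genes = genes, srnas = srnas, truth = truth)
  })
}

#' Write a generated locus set to disk
#'
#' Serializes the output of [generate_locus_set()] as plain-text files:
#' `genome.fa`, `genes.gff3`, `srnas.bed` (BED6, unknown strand as `.`)
#' and `truth.tsv`.
#'
#' @param locus_set Output of [generate_locus_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_locus_set <- function(locus_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(locus_set$genome, file.path(dir, "genome.fa"),
                              width = 70L)
  write_gff3(locus_set$genes, file.path(dir, "genes.gff3"))
  write_bed6(locus_set$srnas, file.path(dir, "srnas.bed"))
  utils::write.table(locus_set$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write gene records to GFF3
#'
#' @param genes `GRanges` with `gene_id` (and optionally `product`)
#'   metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  mc <- S4Vectors::mcols(genes)
  attrs <- paste0("ID=", mc$gene_id)
  if (!is.null(mc$product)) {
    attrs <- ifelse(nzchar(mc$product),
                    paste0(attrs, ";product=", mc$product), attrs)
  }
  lines <- paste(as.character(GenomicRanges::seqnames(genes)),
                 "asrnascreen", "gene",
                 GenomicRanges::start(genes), GenomicRanges::end(genes),
                 ".", as.character(GenomicRanges::strand(genes)), ".",
                 attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Generate expression and binding-evidence tables with planted structure
#'
#' Genes flagged `selected_fold` in the ground truth receive one time point
#' with a fold change drawn in `[fold_above, fold_above + 1]` (above the
#' screen's threshold) and the rest below; unflagged genes receive only
#' below-threshold folds of random sign (magnitude in `[1, fold_below]`).
#' Genes flagged `selected_bard` receive an enrichment ratio in `[2, 250]`;
#' others are absent from the binding table.
#'
#' @param truth Ground-truth data.frame from [generate_locus_set()] (needs
#'   `gene_id`, `selected_fold`, `selected_bard`).
#' @param seed Integer seed.
#' @param fold_above Lower bound of planted above-threshold folds
#'   (default 3).
#' @param fold_below Upper bound of planted below-threshold fold magnitudes
#'   (default 1.5). Must be strictly less than `fold_above`.
#' @param time_points Column names of the fold table
#'   (default `t24`, `t48`, `t72`).
#' @return List of data.frames `de` (gene_id + one column per time point)
#'   and `bard` (gene_id, bard_ratio).
#' @export
generate_expression_tables <- function(truth, seed, fold_above = 3.0,
                                       fold_below = 1.5,
                                       time_points = c("t24", "t48", "t72")) {
  if (fold_above <= fold_below) {
    stop("generation error: fold_above must exceed fold_below ",
         "(no separation between planted classes)", call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(truth)
    below <- function(k) {
      stats::runif(k, 1, fold_below) * sample(c(-1, 1), k, replace = TRUE)
    }
    de <- data.frame(gene_id = truth$gene_id, stringsAsFactors = FALSE)
    for (tp in time_points) de[[tp]] <- if (n) below(n) else numeric(0)
    for (i in seq_len(n)) {
      if (isTRUE(truth$selected_fold[i])) {
        tp <- sample(time_points, 1L)
        de[i, tp] <- stats::runif(1, fold_above, fold_above + 1)
      }
    }
    sel_b <- which(truth$selected_bard)
    bard <- data.frame(gene_id = truth$gene_id[sel_b],
                       bard_ratio = if (length(sel_b))
                         round(stats::runif(length(sel_b), 2, 250), 1)
                       else numeric(0),
                       stringsAsFactors = FALSE)
    list(de = de, bard = bard)
  })
}

#' Generate a northern band-intensity table with planted response structure
#'
#' Emulates a developmental time course (vegetative mycelium at 24 h,
#' aerial mycelium at 48 h, spores at 72 h) measured in the wild-type and
#' rnc strains. Each feature's wild-type level is `baseline`; its rnc level
#' is `baseline` times the planted ratio for its response category
#' (`increased_in_rnc`: `ratio_increased`; `decreased_in_rnc`:
#' `ratio_decreased`; `unchanged`: 1; `not_detected`: both strains 0).
#' Band signals get multiplicative lognormal noise of the stated
#' coefficient of variation (positive support; `noise_cv = 0` reproduces
#' the planted ratios exactly); 5S control lanes are included.
#'
#' @param truth Data.frame with columns `feature_id` and `response`.
#' @param seed Integer seed.
#' @param noise_cv Coefficient of variation of band noise (default 0.05).
#' @param time_points_h Shared time points in hours (default 24, 48, 72).
#' @param baseline Wild-type normalized level (default 0.2).
#' @param ratio_increased,ratio_decreased Planted rnc/wt ratios
#'   (defaults 4 and 0.25).
#' @param control_level 5S control signal per lane (default 1000).
#' @return Data.frame with columns `feature_id`, `strain`, `time_point_h`,
#'   `band_signal`, `control_signal`.
#' @export
generate_northern_table <- function(truth, seed, noise_cv = 0.05,
                                    time_points_h = c(24, 48, 72),
                                    baseline = 0.2,
                                    ratio_increased = 4,
                                    ratio_decreased = 0.25,
                                    control_level = 1000) {
  stopifnot(noise_cv >= 0, baseline > 0)
  ratio_of <- c(increased_in_rnc = ratio_increased,
                decreased_in_rnc = ratio_decreased,
                unchanged = 1, not_detected = NA_real_)
  bad <- setdiff(unique(truth$response), names(ratio_of))
  if (length(bad)) {
    stop("unknown response category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    s <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    noise <- function(k) {
      if (s == 0) rep(1, k) else stats::rlnorm(k, -s^2 / 2, s)
    }
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      r <- ratio_of[[truth$response[i]]]
      for (strain in c("wt", "rnc")) {
        level <- if (is.na(r)) 0
                 else if (strain == "wt") baseline else baseline * r
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = truth$feature_id[i],
          strain = strain,
          time_point_h = time_points_h,
          band_signal = level * control_level * noise(length(time_points_h)),
          control_signal = control_level,
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(feature_id = character(), strain = character(),
                 time_point_h = numeric(), band_signal = numeric(),
                 control_signal = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
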