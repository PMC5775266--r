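ANTISENSE_CATEGORIES <- c("CIS_AS_5PRIME", "CUTORNA", "CIS_AS_OTHER",
                          "AMBIGUOUS")

#' Screen parameters
#'
#' @param fold_threshold Strict lower bound on the signed fold change for a
#'   gene to count as "increased" in the RNase III deletion mutant
#'   (default 2: "more than two-fold" read as a strict inequality, so a
#'   fold of exactly 2.00 does not qualify).
#' @param selector_mode `"fold_or_bard"` (default; union of the two
#'   criteria), `"fold_only"` or `"bard_only"`.
#' @param bard_min_ratio Minimal RNase III co-immunoprecipitation (BARD)
#'   enrichment ratio to count a gene as bound (default 1).
#' @param strict Use strict `>` for the fold comparison (default `TRUE`);
#'   set `FALSE` for `>=` in sensitivity analyses.
#' @return An object of class `screen_params`.
#' @export
screen_params <- function(fold_threshold = 2.0,
                          selector_mode = c("fold_or_bard", "fold_only",
                                            "bard_only"),
                          bard_min_ratio = 1.0,
                          strict = TRUE) {
  selector_mode <- match.arg(selector_mode)
  if (fold_threshold <= 0 || bard_min_ratio <= 0) {
    stop("fold_threshold and bard_min_ratio must be > 0", call. = FALSE)
  }
  structure(list(fold_threshold = fold_threshold,
                 selector_mode = selector_mode,
                 bard_min_ratio = bard_min_ratio,
                 strict = strict),
            class = "screen_params")
}

#' Select candidate genes from expression and binding evidence
#'
#' A gene qualifies under `fold_only` if the signed fold change at some time
#' point exceeds `fold_threshold` (negative folds, i.e. decreases in the rnc
#' mutant, never qualify); under `bard_only` if its BARD enrichment ratio is
#' present and at least `bard_min_ratio`; under `fold_or_bard` if either
#' holds.
#'
#' @param evidence Data.frame from [read_expression_tables()] (columns
#'   `gene_id`, `bard_ratio`, list-column `fold_changes`).
#' @param params A [screen_params()] object.
#' @return Sorted character vector of selected gene ids.
#' @export
filter_selected <- function(evidence, params = screen_params()) {
  if (nrow(evidence) == 0L) return(character())
  by_fold <- vapply(evidence$fold_changes, function(v) {
    if (length(v) == 0L) return(FALSE)
    if (params$strict) any(v > params$fold_threshold)
    else any(v >= params$fold_threshold)
  }, TRUE)
  by_bard <- !is.na(evidence$bard_ratio) &
    evidence$bard_ratio >= params$bard_min_ratio
  keep <- switch(params$selector_mode,
                 fold_only = by_fold,
                 bard_only = by_bard,
                 fold_or_bard = by_fold | by_bard)
  sort(unique(evidence$gene_id[keep]))
}

#' Run the antisense candidate funnel
#'
#' Stages: all annotated genes -> genes selected by expression/binding
#' evidence -> selected genes with at least one antisense or
#' ambiguous-strand sRNA neighbor -> of those, genes also bound in BARD.
#' Counts are of distinct gene ids: a gene with several partner sRNAs
#' contributes several report rows but one to each count.
#'
#' @param genes,srnas `GRanges` from the annotation readers.
#' @param evidence Data.frame from [read_expression_tables()].
#' @param params A [screen_params()] object.
#' @param classifier_params A [classifier_params()] object.
#' @return An object of class `screen_result`: counts `n_input_genes`,
#'   `n_selected`, `n_with_antisense_neighbor`, `n_also_in_bard`, and
#'   `rows`, one per retained (gene, sRNA) pair with `gene_id`, `srna_id`,
#'   `source`, `category`, `arrows`, `comment`, sorted by gene_id.
#' @export
run_screen <- function(genes, srnas, evidence,
                       params = screen_params(),
                       classifier_params = asrnascreen::classifier_params()) {
  selected <- filter_selected(evidence, params)
  selected <- intersect(selected, S4Vectors::mcols(genes)$gene_id)
  calls <- classify_catalog(genes, srnas, classifier_params)
  calls <- calls[calls$category %in% ANTISENSE_CATEGORIES &
                   calls$gene_id %in% selected, , drop = FALSE]
  in_bard <- evidence$gene_id[!is.na(evidence$bard_ratio) &
                                evidence$bard_ratio >= params$bard_min_ratio]
  rows <- calls
  if (nrow(rows)) {
    if (is.null(rows$source)) rows$source <- NA_character_
    rows$comment <- ifelse(rows$gene_id %in% in_bard, "in BARD", "")
    rows <- rows[, c("gene_id", "srna_id", "source", "category", "arrows",
                     "comment")]
    rows <- rows[order(rows$gene_id, rows$srna_id, method = "radix"), ,
                 drop = FALSE]
    rownames(rows) <- NULL
  } else {
    rows <- data.frame(gene_id = character(), srna_id = character(),
                       source = character(), category = character(),
                       arrows = character(), comment = character(),
                       stringsAsFactors = FALSE)
  }
  structure(list(
    n_input_genes = length(unique(S4Vectors::mcols(genes)$gene_id)),
    n_selected = length(selected),
    n_with_antisense_neighbor = length(unique(calls$gene_id)),
    n_also_in_bard = length(unique(intersect(calls$gene_id, in_bard))),
    rows = rows,
    params = params
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Antisense candidate funnel (distinct genes):\n",
      "  input genes:              ", x$n_input_genes, "\n",
      "  evidence-selected:        ", x$n_selected, "\n",
      "  with antisense neighbor:  ", x$n_with_antisense_neighbor, "\n",
      "  also RNase III-bound:     ", x$n_also_in_bard, "\n",
      "  report rows (pairs):      ", nrow(x$rows), "\n", sep = "")
  invisible(x)
}

#' Count distinct target genes in a pair table
#'
#' A gene--sRNA pair table (such as the packaged Streptomyces coelicolor
#' screen, [asrna_fixture()]) may list a gene several times when multiple
#' sRNAs neighbor it; this counts the distinct putative target genes.
#'
#' @param pairs Data.frame with a `gene_id` column, or a path to a TSV.
#' @return Integer count of distinct gene ids.
#' @export
count_distinct_targets <- function(pairs) {
  if (is.character(pairs)) pairs <- read_checked_tsv(pairs)
  stopifnot("gene_id" %in% names(pairs))
  length(unique(pairs$gene_id))
}

#' Summarize RACE and northern detection outcomes
#'
#' Tabulates 5' RACE, 3' RACE and northern blot detection calls, overall
#' and per set (`experimental`: mRNAs co-precipitated with RNase III;
#' `control`: in-vitro RNase III targets and sigma-factor genes).
#'
#' @param detections Data.frame or TSV path with columns `gene_id`,
#'   `set` (`experimental`/`control`), `race_5prime`, `race_3prime`,
#'   `northern`, each detection column coded `+` or `-`.
#' @return An object of class `detection_summary`: `n_tested`,
#'   `n_5prime_detected`, `n_3prime_detected`, `n_northern_positive`, and
#'   `by_set`, a data.frame with the same counts per set.
#' @examples
#' summarize_detections(asrna_fixture("sco_detection_results.tsv"))
#' @export
summarize_detections <- function(detections) {
  if (is.character(detections)) detections <- read_checked_tsv(detections)
  needed <- c("gene_id", "set", "race_5prime", "race_3prime", "northern")
  missing <- setdiff(needed, names(detections))
  if (length(missing)) {
    stop("detection table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(detections$set), c("experimental", "control"))
  if (length(bad)) {
    stop("unknown set label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  plus <- function(x) sum(trimws(x) == "+")
  count_block <- function(d) {
    c(n_tested = nrow(d),
      n_5prime_detected = plus(d$race_5prime),
      n_3prime_detected = plus(d$race_3prime),
      n_northern_positive = plus(d$northern))
  }
  overall <- count_block(detections)
  sets <- c("experimental", "control")
  by_set <- do.call(rbind, lapply(sets, function(s) {
    as.data.frame(as.list(count_block(
      detections[detections$set == s, , drop = FALSE])))
  }))
  by_set <- cbind(set = sets, by_set)
  structure(c(as.list(overall), list(by_set = by_set)),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat("Detection summary: ", x$n_tested, " genes tested; ",
      x$n_5prime_detected, " with a 5' RACE-detected antisense transcript; ",
      x$n_3prime_detected, " with a 3' end; ",
      x$n_northern_positive, " northern-positive.\n", sep = "")
  print(x$by_set, row.names = FALSE)
  invisible(x)
}

#' Path to a packaged fixture table
#'
#' Plain-text tables shipped with the package:
#' `sco_gene_srna_pairs.tsv` -- the curated Streptomyces coelicolor screen
#' of genes up-regulated in the rnc mutant and their antisense/adjacent
#' sRNA neighbors (49 gene--sRNA rows, with orientation category and arrow
#' notation); `sco_detection_results.tsv` -- per-gene RACE and northern
#' outcomes of the 30-gene experimental/control panel, with BARD enrichment
#' ratios and rnc-mutant fold changes.
#'
#' @param file Fixture file name; with no argument, lists available files.
#' @return Absolute path to the file.
#' @export
asrna_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "asrnascreen")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop("no packaged fixture '", file, "'; available: ",
         paste(list.files(dir), collapse = ", "), call. = FALSE)
  }
  path
}
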