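test_that("evidence filter applies strict signed fold and BARD criteria", {
  ev <- make_evidence(
    c("A", "B", "C", "D", "E"),
    list(c(t1 = 2.41), c(t1 = 1.62), c(t1 = -2.14), c(t1 = 2.00),
         c(t1 = 1.22)),
    bard = c(NA, NA, NA, NA, 122))
  expect_equal(filter_selected(ev, screen_params(selector_mode = "fold_only")),
               "A")
  ## exactly 2.00 is excluded under the strict "more than two-fold" reading
  expect_false("D" %in%
    filter_selected(ev, screen_params(selector_mode = "fold_only")))
  expect_true("D" %in%
    filter_selected(ev, screen_params(selector_mode = "fold_only",
                                      strict = FALSE)))
  ## a negative fold never counts as increased, but BARD can admit the gene
  expect_equal(filter_selected(ev, screen_params(selector_mode = "bard_only")),
               "E")
  expect_setequal(
    filter_selected(ev, screen_params(selector_mode = "fold_or_bard")),
    c("A", "E"))
})

test_that("fold_or_bard equals the union of the single modes and thresholds are monotone", {
  set.seed(31)
  n <- 60
  ev <- make_evidence(
    sprintf("G%02d", seq_len(n)),
    lapply(seq_len(n), function(i)
      stats::setNames(round(runif(3, -4, 4), 2), c("t1", "t2", "t3"))),
    bard = ifelse(runif(n) < 0.4, round(runif(n, 0.2, 50), 1), NA))
  ev$fold_changes <- I(lapply(ev$fold_changes,
                              function(v) v[abs(v) >= 1 & v != 0]))
  both <- filter_selected(ev, screen_params(selector_mode = "fold_or_bard"))
  expect_setequal(
    both,
    union(filter_selected(ev, screen_params(selector_mode = "fold_only")),
          filter_selected(ev, screen_params(selector_mode = "bard_only"))))
  for (thr in c(1.5, 2, 3, 4)) {
    sel <- filter_selected(ev, screen_params(fold_threshold = thr,
                                             selector_mode = "fold_only"))
    if (thr > 1.5) expect_true(all(sel %in% prev))
    prev <- sel
  }
})

test_that("the candidate funnel counts distinct genes at each stage", {
  ## 5 genes; 2 pass the filter; 1 of those has an antisense neighbor,
  ## and that one is also in BARD -> funnel (5, 2, 1, 1)
  genes <- c(mk_gene("c", 101, 400, "+", "g1"),
             mk_gene("c", 1001, 1300, "+", "g2"),
             mk_gene("c", 2001, 2300, "+", "g3"),
             mk_gene("c", 3001, 3300, "+", "g4"),
             mk_gene("c", 4001, 4300, "+", "g5"))
  srnas <- c(mk_srna("c", 90, 180, "-", "s1"),      # antisense to g1
             mk_srna("c", 2050, 2150, "+", "s2"))   # sense overlap on g3
  ev <- make_evidence(c("g1", "g2", "g3", "g4", "g5"),
                      list(c(t1 = 3.5), c(t1 = 2.8), c(t1 = 1.1),
                           c(t1 = -3.0), c(t1 = 1.9)),
                      bard = c(15, NA, 20, NA, NA))
  res <- run_screen(genes, srnas, ev,
                    screen_params(selector_mode = "fold_only"))
  expect_equal(res$n_input_genes, 5)
  expect_equal(res$n_selected, 2)
  expect_equal(res$n_with_antisense_neighbor, 1)
  expect_equal(res$n_also_in_bard, 1)
  expect_equal(res$rows$gene_id, "g1")
  expect_equal(res$rows$comment, "in BARD")
  ## funnel is monotone non-increasing
  with(res, expect_true(n_also_in_bard <= n_with_antisense_neighbor &&
                          n_with_antisense_neighbor <= n_selected &&
                          n_selected <= n_input_genes))
  ## no sRNAs at all: the late stages empty out
  res0 <- run_screen(genes, srnas[0], ev,
                     screen_params(selector_mode = "fold_only"))
  expect_equal(res0$n_with_antisense_neighbor, 0)
  expect_equal(res0$n_also_in_bard, 0)
  expect_equal(nrow(res0$rows), 0)
})

test_that("a gene with several partner sRNAs adds rows but not counts", {
  genes <- mk_gene("c", 1001, 1400, "+", "g1")
  srnas <- c(mk_srna("c", 980, 1060, "-", "s1"),
             mk_srna("c", 1350, 1450, "-", "s2"))
  ev <- make_evidence("g1", list(c(t1 = 4)), bard = 3)
  res <- run_screen(genes, srnas, ev)
  expect_equal(nrow(res$rows), 2)
  expect_equal(res$n_with_antisense_neighbor, 1)
  expect_equal(res$n_also_in_bard, 1)
})

test_that("the packaged pair table lists 49 pairs over 45 distinct target genes", {
  pairs <- read.delim(asrna_fixture("sco_gene_srna_pairs.tsv"),
                      comment.char = "#")
  expect_equal(nrow(pairs), 49)
  expect_equal(count_distinct_targets(pairs), 45)
  expect_equal(count_distinct_targets(asrna_fixture("sco_gene_srna_pairs.tsv")),
               45)
})

test_that("detection summaries count RACE and northern outcomes per set", {
  s <- summarize_detections(asrna_fixture("sco_detection_results.tsv"))
  expect_equal(s$n_tested, 30)
  expect_equal(s$n_5prime_detected, 22)
  expect_equal(s$n_northern_positive, 18)
  exp_row <- s$by_set[s$by_set$set == "experimental", ]
  expect_equal(exp_row$n_tested, 17)
  expect_equal(exp_row$n_5prime_detected, 17)
  expect_equal(exp_row$n_3prime_detected, 16)
  expect_true(s$n_northern_positive <= s$n_5prime_detected)

  empty <- data.frame(gene_id = character(), set = character(),
                      race_5prime = character(), race_3prime = character(),
                      northern = character())
  s0 <- summarize_detections(empty)
  expect_equal(s0$n_tested, 0)
  expect_equal(s0$n_5prime_detected, 0)

  bad <- data.frame(gene_id = "g", set = "mystery", race_5prime = "+",
                    race_3prime = "+", northern = "+")
  expect_error(summarize_detections(bad), "unknown set label")
})
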