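## deterministic GC-balanced test contig
make_locus <- function(n = 200, seed = 5) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("oligo metrics follow the Wallace rule", {
  m <- oligo_metrics("ATGC")
  expect_equal(m$tm_celsius, 12)
  expect_equal(m$gc_fraction, 0.5)
  expect_equal(m$reverse_complement, "GCAT")
  expect_equal(oligo_metrics("GGCC")$gc_fraction, 1.0)
  expect_equal(oligo_metrics("ATAT")$tm_celsius, 8)
  expect_equal(oligo_metrics("ATAT")$gc_fraction, 0)
  expect_error(oligo_metrics("ATXG"), "A/C/G/T")
  expect_error(oligo_metrics(""), "A/C/G/T")
})

test_that("RACE oligo design covers the RBS+start window and optimizes Tm", {
  genome <- Biostrings::DNAStringSet(make_locus(200))
  names(genome) <- "chrL"
  gene <- mk_gene("chrL", 101, 180, "+", "gene1")
  cons <- oligo_constraints(tm_min = 40, tm_max = 80, gc_min = 0, gc_max = 1)
  spec <- design_race_oligo(gene, genome, cons)
  expect_s3_class(spec, "oligo_spec")
  ## footprint must contain the whole window [start-15, start+3]
  expect_true(spec$start <= 86 && spec$end >= 104)
  ## self-consistency: the returned oligo passes its own constraints
  m <- oligo_metrics(spec$sequence)
  expect_equal(m$tm_celsius, spec$tm_celsius)
  expect_equal(m$gc_fraction, spec$gc_fraction)
  expect_true(spec$tm_celsius >= cons$tm_min && spec$tm_celsius <= cons$tm_max)
  expect_true(nchar(spec$sequence) >= cons$min_len &&
                nchar(spec$sequence) <= cons$max_len)
  ## plus-strand gene: the oligo is the template substring itself
  expect_equal(spec$sequence,
               substr(as.character(genome[["chrL"]]), spec$start, spec$end))

  ## exhaustive independent scan: no candidate is strictly better
  txt <- as.character(genome[["chrL"]])
  tm_mid <- (cons$tm_min + cons$tm_max) / 2
  best <- NULL
  for (len in cons$min_len:cons$max_len) {
    for (a in 1:(200 - len + 1)) {
      b <- a + len - 1
      if (a > 86 || b < 104) next
      sq <- substr(txt, a, b)
      bases <- strsplit(sq, "")[[1]]
      tm <- 2 * sum(bases %in% c("A", "T")) + 4 * sum(bases %in% c("G", "C"))
      if (tm < cons$tm_min || tm > cons$tm_max) next
      key <- c(abs(tm - tm_mid), len, a)
      if (is.null(best) ||
          key[1] < best[1] ||
          (key[1] == best[1] && key[2] < best[2]) ||
          (key[1] == best[1] && key[2] == best[2] && key[3] < best[3])) {
        best <- key
      }
    }
  }
  expect_equal(abs(spec$tm_celsius - tm_mid), best[1])
  expect_equal(nchar(spec$sequence), best[2])
  expect_equal(spec$start, best[3])
})

test_that("minus-strand design returns the mRNA-sense (reverse-complement) oligo", {
  genome <- Biostrings::DNAStringSet(make_locus(200, seed = 8))
  names(genome) <- "chrL"
  gene <- mk_gene("chrL", 21, 100, "-", "gene1")  # 5' end at 100
  cons <- oligo_constraints(tm_min = 40, tm_max = 80, gc_min = 0, gc_max = 1)
  spec <- design_race_oligo(gene, genome, cons)
  expect_true(spec$start <= 97 && spec$end >= 115)  # window [100-3, 100+15]
  expect_equal(spec$strand, "-")
  fwd <- substr(as.character(genome[["chrL"]]), spec$start, spec$end)
  expect_equal(spec$sequence, oligo_metrics(fwd)$reverse_complement)
})

test_that("design signals missing flank and absence of a solution distinctly", {
  genome <- Biostrings::DNAStringSet("ACGTACGTACGTACGTACGT")
  names(genome) <- "chrL"
  expect_error(design_race_oligo(mk_gene("chrL", 5, 15, "+", "g"), genome),
               "insufficient flank")
  ## homopolymer A: Wallace Tm caps at 2 nt/degree, far below tm_min 55
  polyA <- Biostrings::DNAStringSet(paste(rep("A", 200), collapse = ""))
  names(polyA) <- "chrL"
  expect_null(design_race_oligo(mk_gene("chrL", 101, 150, "+", "g"), polyA,
                                oligo_constraints(tm_min = 55)))
})

test_that("virtual PCR finds the shortest opposing-site product on either strand", {
  set.seed(13)
  template <- make_locus(50, seed = 13)
  fwd <- substr(template, 1, 20)
  rev <- oligo_metrics(substr(template, 33, 50))$reverse_complement
  amp <- predict_amplicon(fwd, rev, template)
  expect_true(amp$found)
  expect_equal(amp$product_length_nt, 50)
  expect_equal(amp$template_start, 1)
  expect_equal(amp$template_end, 50)

  ## strand symmetry: reverse-complement template with swapped primers
  rc <- oligo_metrics(template)$reverse_complement
  amp2 <- predict_amplicon(rev, fwd, rc)
  expect_true(amp2$found)
  expect_equal(amp2$product_length_nt, amp$product_length_nt)

  ## primers in the same orientation never give a product
  amp3 <- predict_amplicon(fwd, substr(template, 31, 48), template)
  expect_false(amp3$found)

  ## two opposing site pairs: the shortest product wins
  t2 <- paste0(template, make_locus(40, seed = 14), substr(template, 31, 50))
  amp4 <- predict_amplicon(fwd, rev, t2)
  expect_true(amp4$found)
  expect_equal(amp4$product_length_nt, 50)
})

test_that("virtual PCR strand symmetry holds on random templates", {
  for (seed in 1:10) {
    template <- make_locus(400, seed = seed)
    fwd <- substr(template, 41, 60)
    rev <- oligo_metrics(substr(template, 301, 320))$reverse_complement
    a <- predict_amplicon(fwd, rev, template)
    b <- predict_amplicon(rev, fwd, oligo_metrics(template)$reverse_complement)
    expect_equal(a$found, b$found)
    if (a$found) expect_equal(a$product_length_nt, b$product_length_nt)
  }
})

test_that("trans-target scanning reports near-identical windows on both strands", {
  set.seed(21)
  bg <- make_locus(5000, seed = 21)
  query <- make_locus(40, seed = 22)
  ## implant verbatim at 2001
  genome <- Biostrings::DNAStringSet(paste0(
    substr(bg, 1, 2000), query, substr(bg, 2041, 5000)))
  names(genome) <- "chrX"
  hits <- find_trans_targets(query, genome, min_identity = 0.9)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2001)
  expect_equal(hits$end, 2040)
  expect_equal(hits$identity_fraction, 1.0)
  expect_equal(hits$strand, "+")

  ## implant with 2 mismatches (identity 0.95)
  mut <- query
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(query, 10, 10))[1]
  substr(mut, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(query, 30, 30))[1]
  genome2 <- Biostrings::DNAStringSet(paste0(
    substr(bg, 1, 2000), mut, substr(bg, 2041, 5000)))
  names(genome2) <- "chrX"
  h2 <- find_trans_targets(query, genome2, min_identity = 0.9)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$identity_fraction, 0.95)
  expect_equal(nrow(find_trans_targets(query, genome2,
                                       min_identity = 0.98)), 0)

  ## reverse-strand implant is found with strand "-"
  rcq <- oligo_metrics(query)$reverse_complement
  genome3 <- Biostrings::DNAStringSet(paste0(
    substr(bg, 1, 2000), rcq, substr(bg, 2041, 5000)))
  names(genome3) <- "chrX"
  h3 <- find_trans_targets(query, genome3, min_identity = 0.9)
  expect_equal(h3$strand, "-")
  expect_equal(h3$start, 2001)

  ## absent query yields an empty result
  none <- find_trans_targets(query,
                             stats::setNames(Biostrings::DNAStringSet(
                               substr(bg, 1, 1000)), "chrX"),
                             min_identity = 0.95)
  expect_equal(nrow(none), 0)
  expect_error(find_trans_targets(query, genome, min_identity = 1.2),
               "min_identity")
})

test_that("at identity 1 the scan equals exact substring search on both strands", {
  set.seed(33)
  genome <- Biostrings::DNAStringSet(make_locus(3000, seed = 33))
  names(genome) <- "chrX"
  txt <- as.character(genome[["chrX"]])
  query <- substr(txt, 501, 530)
  hits <- find_trans_targets(query, genome, min_identity = 1.0)
  ## oracle: plain character search on the text and its reverse complement
  fwd_pos <- gregexpr(query, txt, fixed = TRUE)[[1]]
  fwd_pos <- fwd_pos[fwd_pos > 0]
  rcq <- oligo_metrics(query)$reverse_complement
  rev_pos <- gregexpr(rcq, txt, fixed = TRUE)[[1]]
  rev_pos <- rev_pos[rev_pos > 0]
  expect_setequal(hits$start[hits$strand == "+"], fwd_pos)
  expect_setequal(hits$start[hits$strand == "-"], rev_pos)
  expect_true(all(hits$identity_fraction == 1))
})
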