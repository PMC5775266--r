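#' Basic oligo metrics
#'
#' Wallace-rule melting temperature (2 degC per A/T, 4 degC per G/C), GC
#' fraction and reverse complement. The Wallace rule is deterministic and
#' adequate at primer scale; [design_race_oligo()] accepts any replacement
#' Tm function.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T` (5'->3').
#' @return List with `tm_celsius`, `gc_fraction`, `reverse_complement`.
#' @examples
#' oligo_metrics("ATGC")  # Tm 12, GC 0.5, revcomp "GCAT"
#' @export
oligo_metrics <- function(sequence) {
  check_dna(sequence)
  b <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  at <- sum(b %in% c("A", "T"))
  gc <- sum(b %in% c("G", "C"))
  list(tm_celsius = 2 * at + 4 * gc,
       gc_fraction = gc / length(b),
       reverse_complement = as.character(
         Biostrings::reverseComplement(Biostrings::DNAString(sequence))))
}

check_dna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0L || grepl("[^ACGT]", sequence)) {
    stop("sequence must be a non-empty string over A/C/G/T", call. = FALSE)
  }
  invisible(sequence)
}

#' Oligo design constraints
#'
#' @param min_len,max_len Length bounds in nt (defaults 18, 25).
#' @param tm_min,tm_max Melting-temperature bounds in degC (defaults 55,
#'   65, Wallace rule).
#' @param gc_min,gc_max GC-fraction bounds (defaults 0.4, 0.75).
#' @return An object of class `oligo_constraints`.
#' @export
oligo_constraints <- function(min_len = 18, max_len = 25,
                              tm_min = 55, tm_max = 65,
                              gc_min = 0.4, gc_max = 0.75) {
  stopifnot(min_len <= max_len, tm_min <= tm_max,
            gc_min >= 0, gc_max <= 1, gc_min <= gc_max)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 tm_min = tm_min, tm_max = tm_max,
                 gc_min = gc_min, gc_max = gc_max),
            class = "oligo_constraints")
}

#' Design a RACE primer / northern probe over the RBS and start codon
#'
#' Designs the gene-specific oligo used both to prime reverse transcription
#' of the antisense transcript in 5' RACE and as the northern hybridization
#' probe. The oligo is taken from the mRNA-sense strand (so it base-pairs
#' with, and primes on, the antisense RNA) and its genomic footprint must
#' contain the whole 5' window -- `five_prime_upstream` nt upstream of the
#' start codon through `five_prime_downstream` nt into the CDS,
#' strand-aware. Among candidates meeting all constraints, the one whose
#' Wallace Tm is closest to the midpoint of `[tm_min, tm_max]` wins; ties go
#' to the shorter oligo, then the leftmost genomic position.
#'
#' @param gene Length-1 `GRanges` with `gene_id` metadata.
#' @param genome Named `DNAStringSet` from [read_genome()].
#' @param constraints An [oligo_constraints()] object.
#' @param params A [classifier_params()] object (supplies the 5' window).
#' @param tm_fun Tm function taking a sequence, defaulting to the Wallace
#'   rule of [oligo_metrics()].
#' @param role Reported role of the oligo.
#' @return An object of class `oligo_spec` (`sequence`, `chrom`, `start`,
#'   `end`, `strand`, `tm_celsius`, `gc_fraction`, `role`), or `NULL` if no
#'   candidate satisfies the constraints (a no-solution signal, not an
#'   error). A window extending past the contig edge is an error.
#' @export
design_race_oligo <- function(gene, genome,
                              constraints = oligo_constraints(),
                              params = classifier_params(),
                              tm_fun = NULL,
                              role = "five_prime_race_primer") {
  stopifnot(length(gene) == 1L)
  if (is.null(tm_fun)) tm_fun <- function(s) oligo_metrics(s)$tm_celsius
  chrom <- as.character(GenomicRanges::seqnames(gene))
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not in genome", call. = FALSE)
  }
  chrlen <- Biostrings::nchar(genome[[chrom]])
  gstrand <- as.character(GenomicRanges::strand(gene))
  w <- five_prime_window(GenomicRanges::start(gene),
                         GenomicRanges::end(gene), gstrand, params)
  if (w[1L] < 1L || w[2L] > chrlen) {
    stop("insufficient flank: 5' window [", w[1L], ", ", w[2L],
         "] extends past contig '", chrom, "' (length ", chrlen, ")",
         call. = FALSE)
  }
  wlen <- w[2L] - w[1L] + 1L
  min_len <- max(constraints$min_len, wlen)
  if (min_len > constraints$max_len) {
    return(NULL)  # window wider than the longest admissible oligo
  }
  chrseq <- genome[[chrom]]
  tm_mid <- (constraints$tm_min + constraints$tm_max) / 2
  best <- NULL
  for (len in min_len:constraints$max_len) {
    ## all footprints of this length containing the window
    for (a in max(1L, w[2L] - len + 1L):w[1L]) {
      b <- a + len - 1L
      if (b > chrlen || a > w[1L]) next
      fwd <- as.character(Biostrings::subseq(chrseq, a, b))
      if (grepl("N", fwd, fixed = TRUE)) next
      seq <- if (gstrand == "+") fwd else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
      m <- oligo_metrics(seq)
      tm <- tm_fun(seq)
      if (tm < constraints$tm_min || tm > constraints$tm_max) next
      if (m$gc_fraction < constraints$gc_min ||
          m$gc_fraction > constraints$gc_max) next
      cand <- list(sequence = seq, chrom = chrom, start = a, end = b,
                   strand = gstrand, tm_celsius = tm,
                   gc_fraction = m$gc_fraction, role = role,
                   dist = abs(tm - tm_mid), len = len)
      if (is.null(best) ||
          cand$dist < best$dist ||
          (cand$dist == best$dist && cand$len < best$len) ||
          (cand$dist == best$dist && cand$len == best$len &&
           cand$start < best$start)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$dist <- NULL; best$len <- NULL
  structure(best, class = "oligo_spec")
}

#' @export
print.oligo_spec <- function(x, ...) {
  cat(x$role, ": 5'-", x$sequence, "-3'  [", x$chrom, ":", x$start, "-",
      x$end, " (", x$strand, "), Tm ", x$tm_celsius, " degC, GC ",
      round(100 * x$gc_fraction, 1), "%]\n", sep = "")
  invisible(x)
}

#' Predict an RT-PCR amplicon (virtual PCR)
#'
#' Finds an exact match of the forward primer on the template and an exact
#' match of the reverse complement of the reverse primer downstream of it;
#' the product length is the span from the start of the forward site to the
#' end of the reverse site, inclusive. Both template orientations are
#' searched, so which primer is called "forward" does not matter. When
#' several site pairs exist, the shortest product (the dominant PCR
#' product) is reported.
#'
#' @param fwd,rev Primer sequences (5'->3'), at least 12 nt.
#' @param template Template sequence (string or `DNAString`), e.g. one
#'   chromosome of [read_genome()].
#' @return An object of class `amplicon_prediction`: `found`, and when
#'   found `product_length_nt`, `template_start`, `template_end`,
#'   `template_strand`, `fwd_match_pos`, `rev_match_pos` (positions on the
#'   searched orientation).
#' @export
predict_amplicon <- function(fwd, rev, template) {
  check_dna(fwd); check_dna(rev)
  if (nchar(fwd) < 12L || nchar(rev) < 12L) {
    stop("primers must be at least 12 nt", call. = FALSE)
  }
  if (is.character(template)) template <- Biostrings::DNAString(template)
  tlen <- length(template)

  scan_orientation <- function(subject, strand) {
    fhits <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::DNAString(fwd), subject))
    rpat <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
    rhits <- Biostrings::matchPattern(rpat, subject)
    rstart <- Biostrings::start(rhits); rend <- Biostrings::end(rhits)
    best <- NULL
    for (fs in fhits) {
      fe <- fs + nchar(fwd) - 1L
      ok <- which(rstart > fe & (rend - fs + 1L) >= nchar(fwd) + nchar(rev))
      if (!length(ok)) next
      lens <- rend[ok] - fs + 1L
      k <- ok[which.min(lens)]
      cand <- list(product_length_nt = min(lens), fwd_match_pos = fs,
                   rev_match_pos = rstart[k],
                   template_start = fs, template_end = rend[k],
                   template_strand = strand)
      if (is.null(best) || cand$product_length_nt < best$product_length_nt)
        best <- cand
    }
    best
  }

  plus <- scan_orientation(template, "+")
  minus <- scan_orientation(Biostrings::reverseComplement(template), "-")
  if (!is.null(minus)) {
    ## report the footprint in plus-strand template coordinates
    s <- tlen - minus$template_end + 1L
    e <- tlen - minus$template_start + 1L
    minus$template_start <- s; minus$template_end <- e
  }
  best <- if (is.null(plus)) minus
          else if (is.null(minus)) plus
          else if (minus$product_length_nt < plus$product_length_nt) minus
          else plus
  if (is.null(best)) {
    return(structure(list(found = FALSE), class = "amplicon_prediction"))
  }
  structure(c(list(found = TRUE), best), class = "amplicon_prediction")
}

#' @export
print.amplicon_prediction <- function(x, ...) {
  if (!x$found) cat("no amplicon predicted\n")
  else cat("amplicon: ", x$product_length_nt, " nt [template ",
           x$template_start, "-", x$template_end, " (",
           x$template_strand, ")]\n", sep = "")
  invisible(x)
}

#' Scan a genome for near-identical trans-acting target sites
#'
#' A cis-antisense RNA is perfectly complementary to its own target, but a
#' near-identical copy of its sequence elsewhere in the genome means it may
#' also act on another transcript in trans. This scans every window of
#' query length on both strands for ungapped identity at least
#' `min_identity`; overlapping hits are merged keeping the best.
#'
#' @param query Query sequence (the asRNA), length at least `min_len`.
#' @param genome Named `DNAStringSet`.
#' @param min_identity Minimum ungapped identity fraction in (0, 1]
#'   (default 0.9).
#' @param min_len Minimum query length in nt (default 20).
#' @return Data.frame of hits: `chrom`, `start`, `end`, `strand`,
#'   `identity_fraction`, `matched_length_nt`, ordered by position.
#' @export
find_trans_targets <- function(query, genome, min_identity = 0.9,
                               min_len = 20L) {
  check_dna(query)
  if (min_identity <= 0 || min_identity > 1) {
    stop("min_identity must be in (0, 1]", call. = FALSE)
  }
  qlen <- nchar(query)
  if (qlen < min_len) {
    stop("query shorter than min_len (", min_len, " nt)", call. = FALSE)
  }
  max_mm <- floor((1 - min_identity) * qlen)
  qf <- Biostrings::DNAString(query)
  qr <- Biostrings::reverseComplement(qf)
  hits <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") qf else qr
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mm)
      if (length(m) == 0L) next
      nmm <- Biostrings::neditEndingAt(pat,
                                       subject,
                                       ending.at = Biostrings::end(m),
                                       with.indels = FALSE)
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom,
        start = Biostrings::start(m),
        end = Biostrings::end(m),
        strand = strand,
        identity_fraction = (qlen - nmm) / qlen,
        matched_length_nt = qlen,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity_fraction = numeric(),
                      matched_length_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[out$identity_fraction >= min_identity, , drop = FALSE]
  if (nrow(out) > 1L) {
    ## merge overlapping hits (same chrom+strand), keep the best identity
    out <- out[order(out$chrom, out$strand, -out$identity_fraction,
                     out$start, method = "radix"), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      j <- which(keep & seq_len(nrow(out)) > i &
                   out$chrom == out$chrom[i] & out$strand == out$strand[i] &
                   out$start <= out$end[i] & out$end >= out$start[i])
      keep[j] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$start, out$strand, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
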