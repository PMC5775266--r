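#' @importFrom GenomicRanges GRanges start end strand seqnames mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols<-
NULL

STRAND_LEVELS <- c("+", "-", "*")

## Internal coordinate convention: 1-based, fully inclusive (GFF style).
## BED input is converted at the boundary; unknown strand is "*" and is a
## legal state only for small RNAs.

read_tsv_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

#' Read a gene annotation into a GRanges
#'
#' Reads protein-coding gene features from GFF3 or BED6 into a
#' [GenomicRanges::GRanges] with metadata columns `gene_id` and `product`.
#' Internally all coordinates are 1-based inclusive; BED's 0-based half-open
#' intervals are converted at this boundary. Genes must be stranded: a `.`
#' or missing strand is an error for a gene (unlike small RNAs, where an
#' undetermined strand is a first-class state).
#'
#' @param path Path to the annotation file.
#' @param format Either `"gff3"` or `"bed6"`.
#' @return A `GRanges`, sorted by (chrom, start, gene_id), with metadata
#'   columns `gene_id` (unique) and `product` (possibly empty strings).
#'   For GFF3, only rows whose type column is `gene` or `CDS` are kept and
#'   `ID=`/`product=` attributes are extracted.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chrT\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=SCOT001;product=demo"), gff)
#' read_gene_annotation(gff, "gff3")
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed6")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    return(new_gene_granges(character(), integer(), integer(), character(),
                            character(), character()))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)

  if (format == "gff3") {
    ok <- vapply(fields, length, 1L) >= 9L
    if (any(!ok)) {
      stop("malformed record at line ", tl$lineno[which(!ok)[1L]],
           ": expected 9 tab-separated GFF3 columns", call. = FALSE)
    }
    type <- vapply(fields, `[[`, "", 3L)
    keep <- type %in% c("gene", "CDS")
    fields <- fields[keep]
    lineno <- tl$lineno[keep]
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
    strand <- vapply(fields, `[[`, "", 7L)
    attrs <- vapply(fields, `[[`, "", 9L)
    gene_id <- gff_attribute(attrs, "ID")
    product <- gff_attribute(attrs, "product")
    if (anyNA(gene_id)) {
      stop("malformed record at line ", lineno[which(is.na(gene_id))[1L]],
           ": missing ID attribute", call. = FALSE)
    }
  } else {
    ok <- vapply(fields, length, 1L) >= 6L
    if (any(!ok)) {
      stop("malformed record at line ", tl$lineno[which(!ok)[1L]],
           ": expected 6 tab-separated BED columns", call. = FALSE)
    }
    lineno <- tl$lineno
    chrom <- vapply(fields, `[[`, "", 1L)
    ## BED 0-based half-open -> 1-based inclusive
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))) + 1L
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    gene_id <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
    product <- rep("", length(fields))
  }

  bad <- which(is.na(start) | is.na(end) | end < start | start < 1L)
  if (length(bad)) {
    stop("malformed record at line ", lineno[bad[1L]],
         ": end < start (or non-numeric coordinate) after coordinate",
         " conversion", call. = FALSE)
  }
  badstrand <- which(!strand %in% c("+", "-"))
  if (length(badstrand)) {
    stop("invalid strand '", strand[badstrand[1L]], "' for gene '",
         gene_id[badstrand[1L]], "' at line ", lineno[badstrand[1L]],
         ": genes must be on '+' or '-'", call. = FALSE)
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  new_gene_granges(chrom, start, end, strand, gene_id, product)
}

new_gene_granges <- function(chrom, start, end, strand, gene_id, product) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$product <- product
  sort_by_position(gr, "gene_id")
}

## total, stable order: (chrom, start, id)
sort_by_position <- function(gr, id_col) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr),
             S4Vectors::mcols(gr)[[id_col]], method = "radix")
  gr[o]
}

gff_attribute <- function(attrs, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regexec(pat, attrs)
  g <- regmatches(attrs, m)
  vapply(g, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
}

#' Read a small-RNA catalog (BED6)
#'
#' Small RNA (sRNA) genes come from heterogeneous published catalogs that
#' often do not resolve the transcribed strand; a `.` strand in the BED file
#' is kept as the unknown state (`*`), which downstream classification maps
#' to the "ambiguous" orientation category.
#'
#' @param path BED6 file; column 4 is the sRNA identifier.
#' @param source Citation key of the catalog of origin, attached to every
#'   record.
#' @param status `"predicted"` or `"confirmed"`, attached to every record.
#' @return A `GRanges` with metadata columns `srna_id`, `source`, `status`.
#'   Rows repeating an `srna_id` at identical coordinates are collapsed;
#'   the same id at conflicting coordinates is an error.
#' @export
read_srna_catalog <- function(path, source = "unknown",
                              status = c("predicted", "confirmed")) {
  status <- match.arg(status)
  stopifnot(file.exists(path))
  tl <- read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$srna_id <- character()
    S4Vectors::mcols(gr)$source <- character()
    S4Vectors::mcols(gr)$status <- character()
    return(gr)
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, 1L) >= 6L
  if (any(!ok)) {
    stop("malformed record at line ", tl$lineno[which(!ok)[1L]],
         ": expected 6 tab-separated BED columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))) + 1L
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  srna_id <- vapply(fields, `[[`, "", 4L)
  strand <- vapply(fields, `[[`, "", 6L)
  strand[strand == "."] <- "*"
  bad <- which(is.na(start) | is.na(end) | end < start | start < 1L)
  if (length(bad)) {
    stop("malformed record at line ", tl$lineno[bad[1L]],
         ": end < start after coordinate conversion", call. = FALSE)
  }
  badstrand <- which(!strand %in% STRAND_LEVELS)
  if (length(badstrand)) {
    stop("invalid strand '", strand[badstrand[1L]], "' at line ",
         tl$lineno[badstrand[1L]], call. = FALSE)
  }
  key <- paste(chrom, start, end, strand, sep = ":")
  first <- !duplicated(srna_id)
  conflict <- !first & key != key[match(srna_id, srna_id)]
  if (any(conflict)) {
    stop("duplicate srna_id with conflicting coordinates: ",
         paste(unique(srna_id[conflict]), collapse = ", "), call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(chrom[first],
                               IRanges::IRanges(start[first], end[first]),
                               strand = strand[first])
  S4Vectors::mcols(gr)$srna_id <- srna_id[first]
  S4Vectors::mcols(gr)$source <- rep(source, sum(first))
  S4Vectors::mcols(gr)$status <- rep(status, sum(first))
  sort_by_position(gr, "srna_id")
}

#' Write gene or sRNA records to BED6
#'
#' Converts back to BED's 0-based half-open convention; unknown strand is
#' written as `.`. Round-tripping through [read_gene_annotation()] /
#' [read_srna_catalog()] reproduces identical intervals.
#'
#' @param gr A `GRanges` with a `gene_id` or `srna_id` metadata column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  id <- if ("gene_id" %in% names(mc)) mc$gene_id else mc$srna_id
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  lines <- paste(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr),
                 id, 0L, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file; multi-line records are concatenated.
#' @return A named [Biostrings::DNAStringSet], uppercase, alphabet restricted
#'   to `A`, `C`, `G`, `T`, `N`. Any other character is an error reporting
#'   the record and offending position.
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  seqs <- Biostrings::BStringSet(toupper(as.character(seqs)))
  txt <- as.character(seqs)
  bad <- regexpr("[^ACGTN]", txt)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("invalid sequence character '",
         substr(txt[i], bad[i], bad[i]), "' in record '",
         names(seqs)[i], "' at position ", bad[i], call. = FALSE)
  }
  ## keep only the first whitespace-delimited token of the header
  out <- Biostrings::DNAStringSet(txt)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read and merge differential-expression and RNase III-binding tables
#'
#' The differential-expression table gives signed fold changes of each mRNA
#' in the RNase III deletion (rnc) mutant relative to wild type, one column
#' per time point; the binding table gives the enrichment ratio of the mRNA
#' in the RNase III co-immunoprecipitation (BARD) experiment. The two are
#' merged on `gene_id`; a gene present in only one table keeps the other
#' side absent (`NA`), never zero.
#'
#' @param de_path TSV with a header; first column the gene id, remaining
#'   numeric columns one per time point. `#`-prefixed lines are skipped.
#' @param bard_path TSV with a header; columns `gene_id` (or first column)
#'   and the enrichment ratio in the second column.
#' @return A data.frame with columns `gene_id`, `bard_ratio` and a
#'   list-column `fold_changes` (named numeric vector per gene, absent time
#'   points dropped).
#' @export
read_expression_tables <- function(de_path, bard_path) {
  de <- read_checked_tsv(de_path)
  bard <- read_checked_tsv(bard_path)
  folds <- list()
  if (nrow(de)) {
    tps <- names(de)[-1L]
    for (i in seq_len(nrow(de))) {
      v <- vapply(tps, function(tp) parse_numeric_cell(de[i, tp], de_path,
                                                       i, tp), 0)
      v <- v[!is.na(v)]
      if (any(v == 0)) {
        stop("fold change of 0 for gene '", de[i, 1L], "' in ", de_path,
             ": fold changes must be finite and nonzero", call. = FALSE)
      }
      folds[[as.character(de[i, 1L])]] <- v
    }
  }
  bard_ratio <- numeric(0)
  if (nrow(bard)) {
    bard_ratio <- vapply(seq_len(nrow(bard)), function(i)
      parse_numeric_cell(bard[i, 2L], bard_path, i, names(bard)[2L]), 0)
    names(bard_ratio) <- as.character(bard[[1L]])
    present <- bard_ratio[!is.na(bard_ratio)]
    if (any(present <= 0)) {
      stop("BARD enrichment ratio must be > 0 (gene '",
           names(present)[which(present <= 0)[1L]], "')", call. = FALSE)
    }
  }
  gene_id <- sort(unique(c(names(folds), names(bard_ratio))))
  data.frame(
    gene_id = gene_id,
    bard_ratio = unname(bard_ratio[match(gene_id, names(bard_ratio))]),
    fold_changes = I(lapply(gene_id, function(g) {
      v <- folds[[g]]
      if (is.null(v)) numeric(0) else v
    })),
    stringsAsFactors = FALSE
  )
}

read_checked_tsv <- function(path) {
  stopifnot(file.exists(path))
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
}

parse_numeric_cell <- function(x, path, row, col) {
  x <- trimws(x)
  if (is.na(x) || x == "" || toupper(x) == "NA") return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop("non-numeric value '", x, "' in ", basename(path), " (data row ",
         row, ", column '", col, "')", call. = FALSE)
  }
  v
}
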