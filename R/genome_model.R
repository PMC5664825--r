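#' Genomic interval
#'
#' Lightweight interval on a named sequence. Coordinates are 1-based and
#' inclusive throughout the package (the GFF and Bioconductor convention), so
#' a width-100 exon written `101 200` in GFF3 is stored exactly as
#' `start = 101, end = 200`.
#'
#' @param seq_id Sequence (chromosome/contig) name. Non-empty string.
#' @param start,end Integer coordinates, `1 <= start <= end`.
#' @param strand One of `"+"`, `"-"`, `"*"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "*") {
  if (!is.character(seq_id) || length(seq_id) != 1L || !nzchar(seq_id))
    stop("seq_id must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]")
  if (!strand %in% c("+", "-", "*", "."))
    stop("strand must be one of '+', '-', '*'")
  if (strand == ".") strand <- "*"
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$seq_id, x$start, x$end, x$strand))
  invisible(x)
}

gi_width <- function(x) x$end - x$start + 1L

#' Fraction of one interval covered by another
#'
#' Returns the fraction of `a`'s length that lies inside `b`. Intervals on
#' different sequences never overlap. The function is not symmetric unless
#' the two intervals have equal width; the shared overlap length is, so
#' `overlap_fraction(a, b) * width(a) == overlap_fraction(b, a) * width(b)`.
#'
#' @param a,b `genomic_interval` objects.
#' @return A number in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (gi_width(a) < 1L || gi_width(b) < 1L) stop("zero-length interval")
  if (a$seq_id != b$seq_id) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
  if (ov <= 0L) return(0)
  ov / gi_width(a)
}

#' Interval containment
#'
#' `TRUE` when `inner` lies entirely within `outer` (boundaries included).
#' Strand is ignored: a retrocopy may insert in either orientation relative
#' to its element.
#'
#' @param outer,inner `genomic_interval` objects.
#' @return Logical scalar.
#' @export
gi_contains <- function(outer, inner) {
  outer$seq_id == inner$seq_id &&
    outer$start <= inner$start && inner$end <= outer$end
}

#' Protein-coding gene model
#'
#' One representative transcript per gene: an ordered exon chain and the
#' spliced, strand-corrected coding sequence. Exons are stored in
#' transcription order (the first exon is the 5' exon on the coding strand).
#'
#' @param gene_id Gene identifier.
#' @param seq_id,start,end,strand Span of the gene on the genome.
#' @param exons `data.frame` with columns `start`, `end` (genomic, 1-based
#'   inclusive). May be given in any order; stored in transcription order.
#' @param cds Spliced coding sequence (already strand-corrected), or `NA`
#'   when sequences are not available.
#' @param family Optional family/subgroup label (e.g. `"CNL-G2"`); labels are
#'   inputs here, not computed.
#' @param is_nlr Whether the gene belongs to the NLR family under study.
#'   Defaults to `TRUE` when a family label is present.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, start, end, strand, exons,
                       cds = NA_character_, family = NA_character_,
                       is_nlr = !is.na(family)) {
  span <- genomic_interval(seq_id, start, end, strand)
  exons <- as.data.frame(exons)[, c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1L) stop("gene ", gene_id, ": needs at least one exon")
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start > exons$end))
    stop("gene ", gene_id, ": malformed exon interval")
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("gene ", gene_id, ": overlapping exons")
  if (exons$start[1L] < start || exons$end[nrow(exons)] > end)
    stop("gene ", gene_id, ": exons outside gene span")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id, span = span, exons = exons,
                 cds = cds, family = family, is_nlr = isTRUE(is_nlr)),
            class = "gene_model")
}

n_exons <- function(gene) nrow(gene$exons)

#' Total exonic length of a gene
#' @param gene A `gene_model`.
#' @return Summed exon widths in nucleotides.
#' @export
exonic_length <- function(gene) sum(gene$exons$end - gene$exons$start + 1L)

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d(%s) exons=%d cds=%s family=%s\n",
              x$gene_id, x$span$seq_id, x$span$start, x$span$end,
              x$span$strand, n_exons(x),
              if (is.na(x$cds)) "NA" else paste0(nchar(x$cds), "nt"),
              x$family))
  invisible(x)
}

#' Full-length LTR retrotransposon
#'
#' An element bounded by its paired long terminal repeats. The element span
#' runs from the start of the 5' LTR to the end of the 3' LTR; the internal
#' region is everything between the two repeats.
#'
#' @param element_id Element identifier.
#' @param seq_id Sequence name.
#' @param ltr5_start,ltr5_end,ltr3_start,ltr3_end LTR coordinates;
#'   `ltr5_end < ltr3_start` is required.
#' @param tsd Optional list of two `genomic_interval`s (the target-site
#'   duplication copies flanking the element).
#' @param autonomy `"autonomous"`, `"non_autonomous"` or `"unknown"`.
#' @param strand Element strand.
#' @return An object of class `ltr_element`.
#' @export
ltr_element <- function(element_id, seq_id, ltr5_start, ltr5_end,
                        ltr3_start, ltr3_end, tsd = NULL,
                        autonomy = "unknown", strand = "+") {
  ltr5 <- genomic_interval(seq_id, ltr5_start, ltr5_end, strand)
  ltr3 <- genomic_interval(seq_id, ltr3_start, ltr3_end, strand)
  if (ltr5$end >= ltr3$start)
    stop("element ", element_id, ": 5' LTR must end before the 3' LTR starts")
  autonomy <- match.arg(autonomy, c("autonomous", "non_autonomous", "unknown"))
  structure(list(element_id = element_id,
                 span = genomic_interval(seq_id, ltr5$start, ltr3$end, strand),
                 ltr5 = ltr5, ltr3 = ltr3, tsd = tsd, autonomy = autonomy),
            class = "ltr_element")
}

#' Internal region of an LTR element
#' @param element An `ltr_element`.
#' @return `genomic_interval` between the paired LTRs.
#' @export
internal_region <- function(element) {
  genomic_interval(element$span$seq_id, element$ltr5$end + 1L,
                   element$ltr3$start - 1L, element$span$strand)
}

#' @export
print.ltr_element <- function(x, ...) {
  cat(sprintf("ltr_element %s %s:%d-%d ltr5=[%d,%d] ltr3=[%d,%d] %s\n",
              x$element_id, x$span$seq_id, x$span$start, x$span$end,
              x$ltr5$start, x$ltr5$end, x$ltr3$start, x$ltr3$end, x$autonomy))
  invisible(x)
}

REPEAT_ORDERS <- c("LTR", "DNA", "RC", "LINE", "SINE", "Unknown")

#' Repeat feature table constructor
#'
#' Normalizes a repeat annotation table to the package's column layout and
#' checks the repeat order against the closed vocabulary.
#'
#' @param seq_id,start,end,strand,name Per-feature vectors.
#' @param order Repeat order; one of LTR, DNA, RC, LINE, SINE, Unknown.
#' @param superfamily Superfamily string (e.g. `"Gypsy"`); may be `""`.
#' @return `data.frame` with columns seq_id, start, end, strand, name,
#'   order, superfamily.
#' @export
repeat_features <- function(seq_id = character(), start = integer(),
                            end = integer(), strand = "*",
                            name = "", order = "Unknown", superfamily = "") {
  n <- length(seq_id)
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = rep_len(as.character(strand), n),
                   name = rep_len(as.character(name), n),
                   order = rep_len(as.character(order), n),
                   superfamily = rep_len(as.character(superfamily), n),
                   stringsAsFactors = FALSE)
  if (nrow(df) && !all(df$order %in% REPEAT_ORDERS))
    stop("repeat order outside {", paste(REPEAT_ORDERS, collapse = ", "), "}")
  if (nrow(df) && any(df$start > df$end)) stop("malformed repeat interval")
  df
}

#' Annotation bundle
#'
#' The full input to the detection pipeline: gene models, repeat features,
#' full-length LTR elements and (optionally) the genome sequences. Features
#' must lie on sequences present in `sequences` when sequences are given.
#'
#' @param genes List of [gene_model()] objects.
#' @param repeats [repeat_features()] table.
#' @param ltr_elements List of [ltr_element()] objects.
#' @param sequences Named character vector of nucleotide sequences, or `NULL`.
#' @return An object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(genes = list(), repeats = repeat_features(),
                              ltr_elements = list(), sequences = NULL) {
  stopifnot(is.list(genes), is.data.frame(repeats), is.list(ltr_elements))
  if (!is.null(sequences)) {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be a named character vector")
    check_on <- function(iv, what) {
      if (!iv$seq_id %in% names(sequences))
        stop(what, ": seq_id '", iv$seq_id, "' not among the sequences")
      if (iv$end > nchar(sequences[[iv$seq_id]]))
        stop(what, ": interval end ", iv$end, " beyond end of ", iv$seq_id)
    }
    for (g in genes) check_on(g$span, paste("gene", g$gene_id))
    for (e in ltr_elements) check_on(e$span, paste("element", e$element_id))
    if (nrow(repeats)) {
      bad <- !(repeats$seq_id %in% names(sequences))
      if (any(bad)) stop("repeat on unknown sequence '", repeats$seq_id[bad][1L], "'")
      over <- repeats$end > nchar(sequences)[repeats$seq_id]
      if (any(over)) stop("repeat interval beyond end of its sequence")
    }
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  names(ltr_elements) <- vapply(ltr_elements, `[[`, "", "element_id")
  structure(list(genes = genes, repeats = repeats,
                 ltr_elements = ltr_elements, sequences = sequences),
            class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("annotation_bundle: %d genes, %d repeats, %d LTR elements, %s\n",
              length(x$genes), nrow(x$repeats), length(x$ltr_elements),
              if (is.null(x$sequences)) "no sequences"
              else sprintf("%d sequences (%.0f kb)", length(x$sequences),
                           sum(nchar(x$sequences)) / 1e3)))
  invisible(x)
}

# Spliced, strand-corrected CDS from the genome (exons in transcription order).
splice_cds <- function(gene, sequences) {
  chrom <- sequences[[gene$span$seq_id]]
  ex <- gene$exons[order(gene$exons$start), , drop = FALSE]
  parts <- substring(chrom, ex$start, ex$end)
  s <- paste(parts, collapse = "")
  if (gene$span$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
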