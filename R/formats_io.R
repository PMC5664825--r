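#' Read gene models from GFF3
#'
#' Parses a `gene -> mRNA -> exon/CDS` hierarchy and keeps one representative
#' transcript per gene: the transcript with the longest total CDS (ties broken
#' by smallest start). Exons are returned in transcription order. A family
#' label is read from a `family` attribute on the gene or mRNA record when
#' present (e.g. `family=CNL-G2`); the label marks the gene as belonging to
#' the analysed family.
#'
#' Transcripts whose exons overlap one another are rejected with a warning
#' (and the gene is dropped if no transcript survives); rejected transcript
#' ids are attached as the `"rejections"` attribute so that parsed + rejected
#' always accounts for every input transcript. An exon or CDS whose `Parent`
#' is not a declared mRNA is a structural error and aborts the parse.
#'
#' @param path GFF3 file.
#' @param sequences Optional named character vector of genome sequences; when
#'   given, each gene's spliced strand-corrected CDS is filled in.
#' @return List of [gene_model()] objects, named by gene id.
#' @export
read_gene_models <- function(path, sequences = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  ids <- if ("ID" %in% names(m)) as.character(m$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(m)) {
    vapply(m$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_part <- type %in% c("exon", "CDS")
  tx_ids <- ids[is_tx]

  bad <- which(is_part & !(parents %in% tx_ids))
  if (length(bad)) {
    i <- bad[1L]
    stop("GFF3 structure error: ", type[i], " at ",
         as.character(GenomeInfoDb::seqnames(gr))[i], ":",
         BiocGenerics::start(gr)[i], "-", BiocGenerics::end(gr)[i],
         " has no parent mRNA (Parent=", parents[i], ")")
  }

  seqn <- as.character(GenomeInfoDb::seqnames(gr))
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  strands <- as.character(BiocGenerics::strand(gr))
  fam <- if ("family" %in% names(m)) as.character(m$family) else rep(NA_character_, length(gr))

  genes <- list()
  rejections <- character()
  for (gi in which(is_gene)) {
    gid <- ids[gi]
    txs <- which(is_tx & parents == gid)
    if (!length(txs)) next
    best <- NULL; best_len <- -1L; best_start <- NA_integer_
    for (ti in txs) {
      tid <- ids[ti]
      cds_rows <- which(is_part & type == "CDS" & parents == tid)
      part_rows <- if (length(cds_rows)) cds_rows else which(is_part & parents == tid)
      ex <- data.frame(start = starts[part_rows], end = ends[part_rows])
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
        warning("transcript ", tid, " rejected: overlapping exons")
        rejections <- c(rejections, tid)
        next
      }
      len <- sum(ex$end - ex$start + 1L)
      if (len > best_len || (len == best_len && min(ex$start) < best_start)) {
        best <- ex; best_len <- len; best_start <- min(ex$start)
      }
    }
    if (is.null(best)) {
      warning("gene ", gid, " dropped: no usable transcript")
      next
    }
    g <- gene_model(gid, seqn[gi], starts[gi], ends[gi],
                    if (strands[gi] %in% c("+", "-")) strands[gi] else "+",
                    best, family = fam[gi])
    if (!is.null(sequences)) g$cds <- splice_cds(g, sequences)
    genes[[gid]] <- g
  }
  attr(genes, "rejections") <- rejections
  genes
}

gff3_attr_escape <- function(x) gsub(";", "%3B", gsub("=", "%3D", x, fixed = TRUE), fixed = TRUE)

#' Write gene models to GFF3
#'
#' Emits one `gene -> mRNA -> exon + CDS` block per gene (the representative
#' transcript model this package works with), so that
#' `read_gene_models(write_gene_models(x))` reproduces `x`.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ord <- order(vapply(genes, function(g) g$span$seq_id, ""),
               vapply(genes, function(g) g$span$start, 1L))
  for (g in genes[ord]) {
    s <- g$span
    fam <- if (is.na(g$family)) "" else paste0(";family=", gff3_attr_escape(g$family))
    writeLines(sprintf("%s\tretroscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                       s$seq_id, s$start, s$end, s$strand, g$gene_id, fam), con)
    tid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tretroscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       s$seq_id, s$start, s$end, s$strand, tid, g$gene_id), con)
    ex <- g$exons[order(g$exons$start), , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tretroscan\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         s$seq_id, ex$start[i], ex$end[i], s$strand, tid), con)
      writeLines(sprintf("%s\tretroscan\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         s$seq_id, ex$start[i], ex$end[i], s$strand, tid), con)
    }
  }
  invisible(path)
}

parse_repeat_class <- function(cls) {
  order <- sub("/.*$", "", cls)
  superfam <- ifelse(grepl("/", cls), sub("^[^/]*/", "", cls), "")
  unknown <- !(order %in% setdiff(REPEAT_ORDERS, "Unknown"))
  if (any(unknown)) {
    warning("unknown repeat class string(s): ",
            paste(unique(cls[unknown]), collapse = ", "),
            "; order set to 'Unknown'")
    order[unknown] <- "Unknown"
  }
  list(order = order, superfamily = superfam)
}

#' Read repeat annotations
#'
#' Accepts either the package's own headered TSV
#' (`seq_id start end strand name class`) or a RepeatMasker `.out`-style
#' whitespace table (score, divergence columns, then query, begin, end, left,
#' strand, repeat name, class). The class string (e.g. `"LTR/Gypsy"`,
#' `"DNA/hAT"`, `"RC/Helitron"`) is split into order and superfamily; an
#' unrecognized order is kept with order `"Unknown"` and a warning, so no
#' row is silently dropped.
#'
#' @param path Input table.
#' @return A [repeat_features()] data frame.
#' @export
read_repeat_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(repeat_features())
  if (grepl("^\\s*seq_id\\b", lines[1L])) {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    pc <- parse_repeat_class(df$class)
    return(repeat_features(df$seq_id, df$start, df$end, df$strand,
                           df$name, pc$order, pc$superfamily))
  }
  # .out style: drop header/banner lines, keep rows starting with a number
  keep <- grepl("^\\s*\\d", lines)
  if (!any(keep)) return(repeat_features())
  df <- read.table(text = lines[keep], header = FALSE, fill = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 11L) stop("repeat table: expected >= 11 .out-style columns")
  strand <- ifelse(df[[9L]] == "C", "-", "+")
  pc <- parse_repeat_class(as.character(df[[11L]]))
  repeat_features(as.character(df[[5L]]), df[[6L]], df[[7L]], strand,
                  as.character(df[[10L]]), pc$order, pc$superfamily)
}

#' Write repeat annotations (headered TSV)
#' @param repeats [repeat_features()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_repeat_annotations <- function(repeats, path) {
  df <- repeats[order(repeats$seq_id, repeats$start), , drop = FALSE]
  df$class <- ifelse(nzchar(df$superfamily),
                     paste0(df$order, "/", df$superfamily), df$order)
  write.table(df[, c("seq_id", "start", "end", "strand", "name", "class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read full-length LTR elements from GFF3-like records
#'
#' Expects `LTR_retrotransposon` records with two `long_terminal_repeat`
#' children (and optional `target_site_duplication` children), as produced by
#' LTRharvest-class annotators. An element with fewer or more than two LTR
#' children is not a full-length element and is skipped with a warning (it
#' may still be present in the repeat table as a partial fragment); skipped
#' ids are attached as the `"rejections"` attribute.
#'
#' @param path GFF3 file.
#' @return List of [ltr_element()] objects, named by element id.
#' @export
read_ltr_elements <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  ids <- if ("ID" %in% names(m)) as.character(m$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(m)) {
    vapply(m$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  seqn <- as.character(GenomeInfoDb::seqnames(gr))
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  strands <- as.character(BiocGenerics::strand(gr))

  out <- list()
  rejections <- character()
  for (ei in which(type == "LTR_retrotransposon")) {
    eid <- ids[ei]
    kids <- which(type == "long_terminal_repeat" & parents == eid)
    if (length(kids) != 2L) {
      warning("element ", eid, " skipped: ", length(kids),
              " LTR child(ren), full-length elements need exactly 2")
      rejections <- c(rejections, eid)
      next
    }
    kids <- kids[order(starts[kids])]
    tsd_rows <- which(type == "target_site_duplication" & parents == eid)
    tsd <- if (length(tsd_rows) == 2L) {
      tsd_rows <- tsd_rows[order(starts[tsd_rows])]
      list(genomic_interval(seqn[tsd_rows[1L]], starts[tsd_rows[1L]], ends[tsd_rows[1L]]),
           genomic_interval(seqn[tsd_rows[2L]], starts[tsd_rows[2L]], ends[tsd_rows[2L]]))
    } else NULL
    out[[eid]] <- ltr_element(
      eid, seqn[ei], starts[kids[1L]], ends[kids[1L]],
      starts[kids[2L]], ends[kids[2L]], tsd = tsd,
      strand = if (strands[ei] %in% c("+", "-")) strands[ei] else "+")
  }
  attr(out, "rejections") <- rejections
  out
}

#' Write full-length LTR elements to GFF3
#' @param elements List of [ltr_element()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ltr_elements <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ord <- order(vapply(elements, function(e) e$span$seq_id, ""),
               vapply(elements, function(e) e$span$start, 1L))
  for (e in elements[ord]) {
    s <- e$span
    writeLines(sprintf("%s\tretroscan\tLTR_retrotransposon\t%d\t%d\t.\t%s\t.\tID=%s",
                       s$seq_id, s$start, s$end, s$strand, e$element_id), con)
    writeLines(sprintf("%s\tretroscan\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s",
                       s$seq_id, e$ltr5$start, e$ltr5$end, s$strand, e$element_id), con)
    writeLines(sprintf("%s\tretroscan\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tParent=%s",
                       s$seq_id, e$ltr3$start, e$ltr3$end, s$strand, e$element_id), con)
    if (!is.null(e$tsd)) {
      for (t in e$tsd)
        writeLines(sprintf("%s\tretroscan\ttarget_site_duplication\t%d\t%d\t.\t%s\t.\tParent=%s",
                           t$seq_id, t$start, t$end, s$strand, e$element_id), con)
    }
  }
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write a genome FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path, width = 80L)
  invisible(path)
}

RETRO_CALL_COLS <- c("gene_id", "seq_id", "start", "end", "element_id",
                     "evidence", "parent_id", "parent_coverage",
                     "introns_lost", "autonomy", "polyA", "direct_repeats",
                     "insertion_age_my", "verdict")

#' Write the retroduplication call report
#'
#' One row per finalized call, in deterministic coordinate order
#' (seq id, then start).
#'
#' @param calls Call `data.frame` as produced by the pipeline.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_retro_calls <- function(calls, path) {
  for (cc in setdiff(RETRO_CALL_COLS, names(calls))) calls[[cc]] <- NA
  calls <- calls[order(calls$seq_id, calls$start), RETRO_CALL_COLS, drop = FALSE]
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a retroduplication call report
#' @param path TSV written by [write_retro_calls()].
#' @return Call `data.frame`.
#' @export
read_retro_calls <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(gene_id = "character", seq_id = "character",
                            element_id = "character", parent_id = "character",
                            evidence = "character", autonomy = "character",
                            verdict = "character"))
}

#' Read an annotation bundle from standard files
#'
#' @param genes GFF3 gene models.
#' @param repeats Repeat annotation table ([read_repeat_annotations()]).
#' @param ltr GFF3-like LTR element records, or `NULL`.
#' @param fasta Genome FASTA, or `NULL`.
#' @return An [annotation_bundle()].
#' @export
read_annotation_bundle <- function(genes, repeats = NULL, ltr = NULL, fasta = NULL) {
  sequences <- if (!is.null(fasta)) read_genome_fasta(fasta) else NULL
  annotation_bundle(
    genes = read_gene_models(genes, sequences),
    repeats = if (!is.null(repeats)) read_repeat_annotations(repeats) else repeat_features(),
    ltr_elements = if (!is.null(ltr)) read_ltr_elements(ltr) else list(),
    sequences = sequences)
}
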