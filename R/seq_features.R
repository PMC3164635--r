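# Sequence and annotation I/O plus the interval algebra that derives the
# feature-class partition consumed by the RIP scanner.
#
# Conventions used throughout the package:
#   * a genome is a named character vector of uppercase {A,C,G,T,N} strings,
#     one element per contig;
#   * intervals are data.frames with columns contig, start, end (0-based,
#     half-open) and optionally strand; GFF3 (1-based closed) is converted at
#     the boundary, BED passes through unshifted.

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize and validate a nucleotide sequence
#'
#' Uppercases the sequence and rejects any residue outside `{A,C,G,T,N}`.
#' Silent coercion of unexpected residues would corrupt downstream
#' dinucleotide counts, so anything else is an error.
#'
#' @param seq A single character string.
#' @return The uppercased sequence.
#' @keywords internal
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    stop("sequence contains residues outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  }
  s
}

#' Read a genome from a FASTA file
#'
#' Records are uppercased on read (lowercase repeat-masked residues are kept,
#' just normalized); residues outside `{A,C,G,T,N}` and duplicate record ids
#' are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA record id(s): ", paste(dup, collapse = ", "))
  seqs <- vapply(as.character(set), normalize_seq, character(1))
  names(seqs) <- ids
  seqs
}

#' Write a genome to a FASTA file
#'
#' @param contigs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# -- interval algebra ---------------------------------------------------------

#' Construct an interval table
#'
#' @param contig Contig ids.
#' @param start,end 0-based half-open coordinates.
#' @param strand Optional strand (`+`, `-` or `.`).
#' @return data.frame with columns contig, start, end, strand.
#' @export
intervals <- function(contig = character(), start = integer(), end = integer(),
                      strand = ".") {
  contig <- as.character(contig)
  df <- data.frame(contig = contig,
                   start = as.numeric(start), end = as.numeric(end),
                   strand = rep_len(strand, length(contig)),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$start < 0 | df$start >= df$end)) {
    stop("invalid interval: require 0 <= start < end")
  }
  df
}

.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

.from_iranges <- function(ir, contig) {
  intervals(contig = rep(contig, length(ir)),
            start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Merge overlapping or adjacent intervals
#'
#' Output is sorted and disjoint within each contig; total covered length is
#' preserved and the operation is idempotent.
#'
#' @param df Interval data.frame.
#' @return Merged interval data.frame.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(intervals())
  pieces <- lapply(split(df, df$contig), function(d) {
    .from_iranges(IRanges::reduce(.as_iranges(d)), d$contig[1])
  })
  out <- do.call(rbind, pieces[sort(names(pieces))])
  rownames(out) <- NULL
  out
}

#' Complement an interval set within contig bounds
#'
#' Returns exactly the bases not covered by `df`, per contig.
#'
#' @param df Interval data.frame (single contig or multiple).
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return Interval data.frame covering the uncovered bases.
#' @export
complement_intervals <- function(df, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  if (nrow(df)) {
    bad <- df$end > contig_lengths[df$contig]
    if (any(is.na(bad))) {
      stop("interval on unknown contig: ",
           paste(unique(df$contig[is.na(bad)]), collapse = ", "))
    }
    if (any(bad)) stop("interval beyond contig end")
  }
  out <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    if (len == 0) return(intervals())
    d <- df[df$contig == ct, , drop = FALSE]
    full <- IRanges::IRanges(1L, len)
    comp <- if (nrow(d)) IRanges::setdiff(full, .as_iranges(d)) else full
    .from_iranges(comp, ct)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Extract the sequence of one interval
#'
#' Honors the half-open convention: `extract_sequence("ACGT", 1, 3)` is
#' `"CG"`.
#'
#' @param seq Contig sequence.
#' @param start,end 0-based half-open coordinates.
#' @return Character string.
#' @export
extract_sequence <- function(seq, start, end) {
  stopifnot(length(seq) == 1L)
  if (start < 0 || start >= end || end > nchar(seq)) {
    stop("interval [", start, ",", end, ") outside contig of length ", nchar(seq))
  }
  substr(seq, start + 1L, end)
}

#' Extract sequences for all rows of an interval table
#'
#' @param contigs Named character vector of contig sequences.
#' @param df Interval data.frame.
#' @return Character vector, one element per interval.
#' @export
extract_intervals <- function(contigs, df) {
  if (nrow(df) == 0L) return(character())
  unknown <- setdiff(unique(df$contig), names(contigs))
  if (length(unknown)) stop("unknown contig id(s): ", paste(unknown, collapse = ", "))
  mapply(function(ct, s, e) extract_sequence(contigs[[ct]], s, e),
         df$contig, df$start, df$end, USE.NAMES = FALSE)
}

# -- feature partition --------------------------------------------------------

FEATURE_CLASSES <- c("whole_genome", "coding", "noncoding", "exon", "intron",
                     "multigene", "repeat")

.granges_to_intervals <- function(gr) {
  intervals(contig = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,
            end = GenomicRanges::end(gr))
}

#' Partition a genome into the feature classes scanned for RIP
#'
#' Derives the seven feature classes the RIP summary is reported over: the
#' whole genome, coding regions (CDS union), non-coding regions (complement
#' of gene spans, i.e. intergenic sequence), exons, introns (gene spans minus
#' exons), multigene-family gene spans, and repetitive sequence.
#'
#' @param contigs Named character vector of contig sequences.
#' @param gff3 Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param repeats Optional path to a BED file of repeat intervals
#'   (0-based half-open, passed through unshifted).
#' @param multigene_ids Optional character vector (or path to a one-id-per-line
#'   file) of gene ids belonging to multigene families.
#' @return A named list of merged interval data.frames, one per feature class,
#'   with the contig lengths in `attr(, "contig_lengths")`.
#' @export
partition_from_gff <- function(contigs, gff3, repeats = NULL,
                               multigene_ids = character()) {
  lens <- stats::setNames(nchar(contigs), names(contigs))
  gff <- rtracklayer::import(gff3, format = "gff3")
  ct <- as.character(GenomicRanges::seqnames(gff))
  unknown <- setdiff(unique(ct), names(contigs))
  if (length(unknown)) stop("GFF3 references unknown contig id(s): ",
                            paste(unknown, collapse = ", "))
  if (any(GenomicRanges::start(gff) < 1) ||
      any(GenomicRanges::end(gff) > lens[ct])) {
    stop("GFF3 coordinates out of contig bounds")
  }
  if (length(multigene_ids) == 1L && file.exists(multigene_ids)) {
    multigene_ids <- readLines(multigene_ids)
    multigene_ids <- multigene_ids[nzchar(multigene_ids)]
  }
  type <- as.character(gff$type)
  genes <- gff[type == "gene"]
  exons <- gff[type == "exon"]
  cds <- gff[type == "CDS"]

  gene_iv <- .granges_to_intervals(genes)
  exon_iv <- merge_intervals(.granges_to_intervals(exons))
  coding <- merge_intervals(.granges_to_intervals(cds))
  noncoding <- complement_intervals(merge_intervals(gene_iv), lens)
  # intron = gene span minus exonic bases, computed within the gene footprint
  gene_merged <- merge_intervals(gene_iv)
  intron <- if (nrow(gene_merged)) {
    pieces <- lapply(split(seq_len(nrow(gene_merged)), gene_merged$contig),
                     function(idx) {
      d <- gene_merged[idx, , drop = FALSE]
      e <- exon_iv[exon_iv$contig == d$contig[1], , drop = FALSE]
      .from_iranges(IRanges::setdiff(.as_iranges(d), .as_iranges(e)),
                    d$contig[1])
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  } else intervals()
  mg <- genes[!is.na(genes$ID) & genes$ID %in% multigene_ids]
  multigene <- merge_intervals(.granges_to_intervals(mg))
  rep_iv <- if (!is.null(repeats)) {
    bed <- utils::read.table(repeats, sep = "\t", stringsAsFactors = FALSE)
    iv <- intervals(contig = bed[[1]], start = bed[[2]], end = bed[[3]])
    if (any(!iv$contig %in% names(contigs)) || any(iv$end > lens[iv$contig])) {
      stop("BED interval outside contig bounds")
    }
    merge_intervals(iv)
  } else intervals()

  part <- list(
    whole_genome = intervals(contig = names(contigs), start = 0, end = lens),
    coding = coding,
    noncoding = noncoding,
    exon = exon_iv,
    intron = intron,
    multigene = multigene,
    `repeat` = rep_iv
  )
  attr(part, "contig_lengths") <- lens
  part
}
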