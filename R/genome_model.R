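#' @importFrom methods as is
#' @importFrom stats setNames
#' @importFrom utils head tail write.table
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "intron", "exon", "pseudogene",
                   "spacer")

#' Construct an annotated genome
#'
#' The central container of the package: a DNA sequence (circular by
#' default, as organellar genomes are) plus an ordered table of typed
#' feature annotations. Coordinates are 0-based half-open throughout the
#' package; a feature whose `end` exceeds the genome length denotes a
#' wrap across the origin of a circular genome.
#'
#' @param id character scalar, genome label.
#' @param sequence DNA string over the IUPAC alphabet (upper-cased on
#'   construction).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param features a data frame with columns `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and `kind` (one of `r paste(FEATURE_KINDS,
#'   collapse = ", ")`), 0-based half-open. Sorted by `start` on
#'   construction.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence,
                             topology = c("circular", "linear"),
                             features = empty_features()) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- which(!strsplit(sequence, "", fixed = TRUE)[[1]] %in% IUPAC_CHARS)
  if (length(bad) > 0L) {
    stop("non-IUPAC character in sequence of '", id, "' at position ",
         bad[1], " (1-based): '",
         substr(sequence, bad[1], bad[1]), "'")
  }
  g <- structure(
    list(id = id, sequence = sequence, topology = topology,
         features = validate_features(features, nchar(sequence))),
    class = "annotated_genome"
  )
  g
}

empty_features <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             strand = character(), kind = character(),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, len) {
  features <- as.data.frame(features)
  needed <- c("name", "start", "end", "strand", "kind")
  if (!all(needed %in% names(features))) {
    stop("feature table must have columns: ", paste(needed, collapse = ", "))
  }
  features <- features[needed]
  if (nrow(features) > 0L) {
    if (any(features$start < 0L | features$start >= len)) {
      stop("feature start outside [0, length)")
    }
    if (any(features$end <= features$start)) {
      stop("feature end must exceed start (wrap is encoded as end > length)")
    }
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be + or -")
    if (!all(features$kind %in% FEATURE_KINDS)) {
      stop("unknown feature kind: ",
           paste(setdiff(features$kind, FEATURE_KINDS), collapse = ", "))
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  features
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s, %d bp, %d features\n",
              x$id, x$topology, genome_length(x), nrow(x$features)))
  invisible(x)
}

#' Genome length in base pairs
#' @param genome an [annotated_genome()].
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Read genomes from a FASTA file
#'
#' One [annotated_genome()] per record, features empty. Sequences are
#' upper-cased. Topology defaults to circular (organellar convention) and
#' can be overridden per record with a `topology=linear` tag in the
#' description line, or globally through `topology`.
#'
#' @param path FASTA file (multi-record, wrapped or unwrapped).
#' @param topology default topology for records without a header tag.
#' @return list of `annotated_genome`.
#' @export
read_fasta <- function(path, topology = "circular") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  lapply(seq_along(set), function(i) {
    topo <- topology
    if (grepl("topology=linear", headers[i], fixed = TRUE)) topo <- "linear"
    if (grepl("topology=circular", headers[i], fixed = TRUE)) topo <- "circular"
    annotated_genome(ids[i], as.character(set[[i]]), topology = topo)
  })
}

#' Write genomes to a FASTA file
#' @param genomes an `annotated_genome` or list of them.
#' @param path output file.
#' @export
write_fasta <- function(genomes, path) {
  if (is(genomes, "annotated_genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, function(g)
    paste0(g$id, " topology=", g$topology), "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# GFF3 types not in the closed kind set are mapped through this table;
# anything else is rejected (strict = TRUE) or skipped with a warning.
GFF3_KIND_SYNONYMS <- c(
  gene = "CDS", mRNA = "CDS", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
  intron = "intron", exon = "exon", pseudogene = "pseudogene",
  region = "spacer", intergenic_region = "spacer", spacer = "spacer"
)

#' Attach GFF3 annotations to a genome
#'
#' Coordinates are converted from GFF3 1-based closed to the internal
#' 0-based half-open convention. Feature types are mapped to the closed
#' kind set (`gene`/`mRNA` count as `CDS`); unknown types are an error
#' under `strict = TRUE` and skipped with a warning otherwise.
#'
#' @param path GFF3 file whose seqids match `genome$id`.
#' @param genome the [annotated_genome()] to annotate.
#' @param strict reject unknown feature types instead of skipping them.
#' @return the genome with `features` attached (replacing any present).
#' @export
read_gff3 <- function(path, genome, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  seqids <- as.character(GenomicRanges::seqnames(gr))
  if (length(gr) > 0L && any(seqids != genome$id)) {
    stop("GFF3 seqid(s) ", paste(unique(setdiff(seqids, genome$id)),
                                 collapse = ", "),
         " do not match genome id '", genome$id, "'")
  }
  type <- as.character(gr$type)
  kind <- unname(GFF3_KIND_SYNONYMS[type])
  if (anyNA(kind)) {
    unknown <- unique(type[is.na(kind)])
    if (strict) stop("unknown feature kind(s): ",
                     paste(unknown, collapse = ", "))
    warning("skipping features of unknown kind: ",
            paste(unknown, collapse = ", "))
    keep <- !is.na(kind)
    gr <- gr[keep]; kind <- kind[keep]
  }
  name <- if ("Name" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$Name)
  } else if ("ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else rep(NA_character_, length(gr))
  name[is.na(name)] <- sprintf("feature%03d", which(is.na(name)))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  len <- genome_length(genome)
  if (length(gr) > 0L) {
    if (any(start0 < 0L | start0 >= len)) {
      stop("GFF3 feature start outside genome '", genome$id, "'")
    }
    if (genome$topology == "linear" && any(end0 > len)) {
      stop("GFF3 feature end beyond linear genome '", genome$id, "'")
    }
  }
  genome$features <- validate_features(
    data.frame(name = name, start = start0, end = end0,
               strand = as.character(GenomicRanges::strand(gr)),
               kind = kind, stringsAsFactors = FALSE),
    len
  )
  genome
}

#' Write a genome's features as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3
#' 1-based closed. A wrap-around feature of a circular genome is written
#' with its end beyond the genome length (accepted back by [read_gff3()]).
#'
#' @param genome an [annotated_genome()] with features.
#' @param path output file.
#' @export
write_gff3 <- function(genome, path) {
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = rep(genome$id, nrow(f)),
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand
  )
  gr$type <- f$kind
  gr$Name <- f$name
  suppressWarnings(rtracklayer::export(gr, path, format = "gff3"))
  invisible(path)
}

#' GC content of a genome
#'
#' (G+C)/(A+C+G+T); IUPAC ambiguity codes are excluded from numerator
#' and denominator.
#'
#' @param genome an [annotated_genome()] or a plain DNA string.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(genome) {
  s <- if (is(genome, "annotated_genome")) genome$sequence else toupper(genome)
  if (nchar(s) == 0L) stop("empty sequence")
  counts <- table(factor(strsplit(s, "", fixed = TRUE)[[1]],
                         levels = c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains only ambiguity codes")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Reverse complement of a DNA string
#' @param s DNA string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# kinds that occupy genic space when computing intergenic intervals
genic_kinds <- function(introns_as_intergenic = FALSE) {
  k <- c("CDS", "tRNA", "rRNA", "exon", "pseudogene")
  if (!introns_as_intergenic) k <- c(k, "intron")
  k
}

#' Intergenic intervals of a circular genome
#'
#' The complement, on the circle, of the union of gene-kind features
#' (CDS, tRNA, rRNA, exon; pseudogenes and introns are treated as genic
#' unless `introns_as_intergenic`). A gene-free genome yields a single
#' full-circle interval. Returned intervals are 0-based half-open; a
#' wrap-around interval has `end > length`.
#'
#' @param genome an [annotated_genome()].
#' @param introns_as_intergenic treat intron features as intergenic space.
#' @return data frame with columns `start`, `end`.
#' @export
intergenic_intervals <- function(genome, introns_as_intergenic = FALSE) {
  len <- genome_length(genome)
  f <- genome$features
  f <- f[f$kind %in% genic_kinds(introns_as_intergenic), , drop = FALSE]
  if (nrow(f) == 0L) {
    return(data.frame(start = 0L, end = len))
  }
  # occupancy on the circle; modest genomes only pass through here, and
  # interval merging below handles the general case without a scan
  iv <- data.frame(start = f$start %% len, end = f$end)
  # split wrapping intervals
  wraps <- iv$end > len
  if (any(wraps)) {
    iv <- rbind(
      data.frame(start = iv$start[!wraps], end = iv$end[!wraps]),
      data.frame(start = iv$start[wraps], end = len),
      data.frame(start = 0L, end = iv$end[wraps] - len)
    )
  }
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  # merge overlapping/adjacent
  merged <- list()
  cs <- iv$start[1]; ce <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= ce) {
      ce <- max(ce, iv$end[i])
    } else {
      merged[[length(merged) + 1L]] <- c(cs, ce)
      cs <- iv$start[i]; ce <- iv$end[i]
    }
  }
  merged[[length(merged) + 1L]] <- c(cs, ce)
  m <- do.call(rbind, merged)
  # complement on the circle
  gaps <- data.frame(start = m[, 2][-nrow(m)], end = m[, 1][-1])
  # wrap gap from last end to first start (possibly across origin)
  last_end <- m[nrow(m), 2]; first_start <- m[1, 1]
  if (genome$topology == "circular") {
    if (last_end < len || first_start > 0L) {
      if (last_end >= len && first_start > 0L) {
        gaps <- rbind(data.frame(start = 0L, end = first_start), gaps)
      } else {
        gaps <- rbind(gaps,
                      data.frame(start = last_end,
                                 end = first_start + len))
      }
    }
  } else {
    if (first_start > 0L) gaps <- rbind(data.frame(start = 0L, end = first_start), gaps)
    if (last_end < len) gaps <- rbind(gaps, data.frame(start = last_end, end = len))
  }
  gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
  # a full-circle complement when genes cover nothing was handled above;
  # normalize a trivial [x, x+len) back if it appeared
  rownames(gaps) <- NULL
  gaps
}

#' Rotate a circular genome
#'
#' Moves the origin so that position `offset` becomes position 0. All
#' feature coordinates shift modulo length; wrap-around features are
#' re-encoded with `end > length` as needed. `rotate(rotate(g, k),
#' length - k)` reproduces `g`.
#'
#' @param genome a circular [annotated_genome()].
#' @param offset new origin, `0 <= offset < length`.
#' @export
rotate <- function(genome, offset) {
  len <- genome_length(genome)
  if (genome$topology != "circular") stop("cannot rotate a linear genome")
  if (offset < 0L || offset >= len) stop("offset out of range [0, length)")
  if (offset == 0L) return(genome)
  s <- genome$sequence
  genome$sequence <- paste0(substr(s, offset + 1L, len), substr(s, 1L, offset))
  f <- genome$features
  if (nrow(f) > 0L) {
    width <- f$end - f$start
    f$start <- (f$start - offset) %% len
    f$end <- f$start + width
    genome$features <- validate_features(f, len)
  }
  genome
}

#' Summary statistics for one or more genomes
#'
#' @param genomes an `annotated_genome` or list of them.
#' @return data frame with id, topology, length, GC percent, feature
#'   counts per kind, total features and unique gene names.
#' @export
genome_stats <- function(genomes) {
  if (is(genomes, "annotated_genome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    counts <- table(factor(g$features$kind, levels = FEATURE_KINDS))
    cbind(
      data.frame(id = g$id, topology = g$topology,
                 length = genome_length(g),
                 gc_pct = round_half_up(100 * gc_content(g), 1)),
      as.data.frame.matrix(t(as.matrix(counts))),
      data.frame(n_features = nrow(g$features),
                 n_unique_genes = length(unique(
                   g$features$name[g$features$kind %in%
                                     c("CDS", "tRNA", "rRNA", "pseudogene")])))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a TSV statistics report
#' @param genomes genomes passed to [genome_stats()].
#' @param path output TSV.
#' @export
write_stats_tsv <- function(genomes, path) {
  write.table(genome_stats(genomes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# round half away from zero at d decimals (printed-report convention;
# base round() is banker's)
round_half_up <- function(x, d = 1) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
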