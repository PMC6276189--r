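STOP_AA <- "*"

get_code <- function(genetic_code = "1") {
  if (genetic_code %in% c("1", "standard")) {
    Biostrings::GENETIC_CODE
  } else {
    Biostrings::getGeneticCode(genetic_code)
  }
}

translate_codon <- function(codon, code) {
  aa <- code[codon]
  ifelse(is.na(aa), "X", unname(aa))
}

to_rna <- function(x) gsub("T", "U", x, fixed = TRUE)

#' Predict C-to-U / U-to-C RNA editing sites in an organellar CDS
#'
#' Comparative prediction: the query CDS is translated, each query
#' codon is mapped to reference residues through global protein
#' alignments against every reference, and a site is emitted when the
#' query residue differs from the strict-majority reference consensus
#' and a single C-to-U or U-to-C substitution at one codon position
#' restores the consensus residue. Internal stop codons removable by a
#' single edit are reported as `orf_restoring` even without a consensus
#' call when the repair is unambiguous; an ACG start codon edited to AUG
#' is reported as `start_gain`; a codon aligned to a reference stop and
#' editable to a stop (CAA/CAG to UAA/UAG, CGA to UGA) as `stop_gain`.
#' References aligning below `min_ref_identity` are ignored. Indel
#' columns of the alignment are skipped — no calls are made within them.
#'
#' @param query_cds DNA string; length must be a multiple of 3 unless
#'   `orf_broken = TRUE`, in which case the reading frame is chosen by
#'   best alignment against the first reference.
#' @param reference_proteins character vector of amino-acid strings
#'   (may include a trailing `*`).
#' @param genetic_code NCBI code id; `"1"`/`"standard"` (the plant
#'   organellar default).
#' @param gene gene name recorded in the output.
#' @param orf_broken allow a query whose length is not a multiple of 3.
#' @param min_ref_identity minimum protein alignment identity for a
#'   reference to vote in the consensus.
#' @return data frame of sites: `gene`, `cds_pos` (0-based), `codon_index`
#'   (0-based), `codon_pos` (0/1/2), `direction` (`"C2U"`/`"U2C"`),
#'   `codon_before`, `codon_after` (RNA), `aa_before`, `aa_after`,
#'   `effect`.
#' @export
predict_editing_sites <- function(query_cds, reference_proteins,
                                  genetic_code = "1", gene = "gene",
                                  orf_broken = FALSE,
                                  min_ref_identity = 0.5) {
  if (length(reference_proteins) == 0L) stop("no reference proteins given")
  code <- get_code(genetic_code)
  q <- toupper(gsub("U", "T", query_cds, fixed = TRUE))
  if (nchar(q) %% 3L != 0L) {
    if (!orf_broken) {
      stop("query CDS length for '", gene, "' is not a multiple of 3; ",
           "set orf_broken = TRUE to pick a frame from the alignment")
    }
    q <- pick_frame(q, reference_proteins[[1]], code)
  }
  ncod <- nchar(q) %/% 3L
  codons <- substring(q, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  qaa <- translate_codon(codons, code)
  # residues of each reference aligned to each query codon
  votes <- matrix(NA_character_, nrow = ncod,
                  ncol = length(reference_proteins))
  for (r in seq_along(reference_proteins)) {
    mapped <- align_ref(qaa, toupper(reference_proteins[[r]]))
    if (is.null(mapped)) next
    ident <- mean(mapped == qaa, na.rm = TRUE)
    if (is.nan(ident) || ident < min_ref_identity) next
    votes[, r] <- mapped
  }
  consensus <- apply(votes, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_character_)
    t <- sort(table(v), decreasing = TRUE)
    if (t[1] * 2L > length(v)) names(t)[1] else NA_character_
  })
  if (all(is.na(votes)) && ncod > 0L) {
    stop("no reference for '", gene,
         "' aligns at the required identity — reference/query ",
         "translations irreconcilable")
  }
  sites <- list()
  emit <- function(i, pos, newbase, effect) {
    cod <- codons[i]
    base <- substr(cod, pos + 1L, pos + 1L)
    after <- cod
    substr(after, pos + 1L, pos + 1L) <- newbase
    sites[[length(sites) + 1L]] <<- data.frame(
      gene = gene, cds_pos = 3L * (i - 1L) + pos, codon_index = i - 1L,
      codon_pos = pos,
      direction = if (base == "C") "C2U" else "U2C",
      codon_before = to_rna(cod), codon_after = to_rna(after),
      aa_before = qaa[i], aa_after = translate_codon(after, code),
      effect = effect, stringsAsFactors = FALSE)
  }
  for (i in seq_len(ncod)) {
    cons <- consensus[i]
    cand <- single_edit_candidates(codons[i], code)
    if (!is.na(cons) && qaa[i] != cons) {
      hit <- cand[cand$aa == cons, , drop = FALSE]
      if (nrow(hit) > 0L) {
        pos <- hit$pos[1]   # lowest codon position on ties
        effect <- if (cons == STOP_AA) "stop_gain"
        else if (qaa[i] == STOP_AA) "orf_restoring"
        else if (i == 1L && codons[i] == "ACG" &&
                 hit$codon[1] == "ATG") "start_gain"
        else "missense"
        emit(i, pos, hit$base[1], effect)
      }
    } else if (is.na(cons) && qaa[i] == STOP_AA && i < ncod) {
      # unambiguous repair of an internal stop without a consensus call
      fix <- cand[cand$aa != STOP_AA, , drop = FALSE]
      if (nrow(fix) == 1L) emit(i, fix$pos[1], fix$base[1], "orf_restoring")
    }
  }
  if (length(sites) == 0L) {
    return(data.frame(gene = character(), cds_pos = integer(),
                      codon_index = integer(), codon_pos = integer(),
                      direction = character(), codon_before = character(),
                      codon_after = character(), aa_before = character(),
                      aa_after = character(), effect = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  out
}

# all codons reachable from `codon` by one C<->T substitution
single_edit_candidates <- function(codon, code) {
  rows <- list()
  for (pos in 0:2) {
    b <- substr(codon, pos + 1L, pos + 1L)
    nb <- if (b == "C") "T" else if (b == "T") "C" else next
    new <- codon
    substr(new, pos + 1L, pos + 1L) <- nb
    rows[[length(rows) + 1L]] <- data.frame(
      pos = pos, base = nb, codon = new,
      aa = translate_codon(new, code), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(pos = integer(), base = character(),
                      codon = character(), aa = character()))
  }
  do.call(rbind, rows)
}

# global protein alignment of query AA vs one reference; returns the
# reference residue aligned to each query position (NA at indels) or
# NULL if the alignment is degenerate
align_ref <- function(qaa, ref) {
  # a terminal reference stop stays alignable (BLOSUM62 scores "*"),
  # so a query codon opposite it can be called as a stop_gain edit
  if (nchar(ref) == 0L || length(qaa) == 0L) return(NULL)
  qstr <- paste(qaa, collapse = "")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qstr), Biostrings::AAString(ref),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  mapped <- rep(NA_character_, length(qaa))
  qi <- 0L
  for (col in seq_along(pa)) {
    if (pa[col] != "-") {
      qi <- qi + 1L
      if (sa[col] != "-") mapped[qi] <- sa[col]
    }
  }
  mapped
}

pick_frame <- function(q, ref, code) {
  best <- NULL; best_score <- -Inf
  for (f in 0:2) {
    sub <- substr(q, f + 1L, f + (nchar(q) - f) %/% 3L * 3L)
    ncod <- nchar(sub) %/% 3L
    if (ncod == 0L) next
    aa <- translate_codon(substring(sub, 3L * seq_len(ncod) - 2L,
                                    3L * seq_len(ncod)), code)
    mapped <- align_ref(aa, ref)
    score <- if (is.null(mapped)) -Inf else sum(mapped == aa, na.rm = TRUE)
    if (score > best_score) { best_score <- score; best <- sub }
  }
  if (is.null(best)) stop("could not choose a reading frame")
  best
}

#' Summarize predicted editing sites
#'
#' Accepts either a site table from [predict_editing_sites()] or a pair
#' of counts `c(n_c2u, n_u2c)`. Percentages are computed from the
#' counts and rounded half-up to one decimal; with zero total they are
#' reported as `NA` (undefined), never 0/0.
#'
#' @param sites site data frame, or integer vector `c(n_c2u, n_u2c)`.
#' @param total_cds_len total CDS length surveyed, bp (for the density).
#' @param gene_cds_len optional named vector of per-gene CDS lengths for
#'   the per-gene table.
#' @return object of class `editing_summary`: `n_total`, `n_c2u`,
#'   `n_u2c`, `pct_c2u`, `pct_u2c`, `total_cds_len`, `density`
#'   (sites/bp), `per_gene` (or `NULL`).
#' @export
summarize_editing <- function(sites, total_cds_len = NA_integer_,
                              gene_cds_len = NULL) {
  per_gene <- NULL
  if (is.data.frame(sites)) {
    n_c2u <- sum(sites$direction == "C2U")
    n_u2c <- sum(sites$direction == "U2C")
    if (nrow(sites) > 0L) {
      tab <- table(sites$gene)
      per_gene <- data.frame(gene = names(tab),
                             n_sites = as.integer(tab),
                             stringsAsFactors = FALSE)
      per_gene$cds_len <- if (!is.null(gene_cds_len)) {
        as.integer(gene_cds_len[per_gene$gene])
      } else NA_integer_
      per_gene$pct_altered <- round_half_up(
        100 * per_gene$n_sites / per_gene$cds_len, 1)
    }
  } else {
    stopifnot(length(sites) == 2L)
    if (any(sites < 0)) stop("negative counts")
    n_c2u <- as.integer(sites[1]); n_u2c <- as.integer(sites[2])
  }
  n_total <- n_c2u + n_u2c
  pct_c2u <- if (n_total > 0L) round_half_up(100 * n_c2u / n_total, 1) else NA_real_
  pct_u2c <- if (n_total > 0L) round_half_up(100 * n_u2c / n_total, 1) else NA_real_
  structure(list(n_total = n_total, n_c2u = n_c2u, n_u2c = n_u2c,
                 pct_c2u = pct_c2u, pct_u2c = pct_u2c,
                 total_cds_len = total_cds_len,
                 density = if (!is.na(total_cds_len) && total_cds_len > 0) {
                   n_total / total_cds_len
                 } else NA_real_,
                 per_gene = per_gene),
            class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(sprintf("<editing_summary> %d sites: %d C-to-U (%s%%), %d U-to-C (%s%%)\n",
              x$n_total, x$n_c2u, format(x$pct_c2u), x$n_u2c,
              format(x$pct_u2c)))
  if (!is.na(x$density)) {
    cat(sprintf("  density: %.5f sites/bp over %d bp CDS\n",
                x$density, x$total_cds_len))
  }
  invisible(x)
}

#' Ratio of editing-site densities between two summaries
#'
#' @param summaryA,summaryB [summarize_editing()] objects with defined
#'   densities (B's nonzero).
#' @return densityA / densityB, rounded half-up to one decimal.
#' @export
editing_density_ratio <- function(summaryA, summaryB) {
  da <- summaryA$density; db <- summaryB$density
  if (is.na(da) || is.na(db)) stop("both densities must be defined")
  if (db == 0) stop("denominator density is zero")
  round_half_up(da / db, 1)
}

#' Write an editing-site table and summary as TSV
#' @param sites site data frame.
#' @param summary an `editing_summary`.
#' @param sites_path,summary_path output TSV paths.
#' @export
write_editing_tsv <- function(sites, summary, sites_path, summary_path) {
  write.table(sites, sites_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  s <- summary
  df <- data.frame(n_total = s$n_total, n_c2u = s$n_c2u, n_u2c = s$n_u2c,
                   pct_c2u = s$pct_c2u, pct_u2c = s$pct_u2c,
                   total_cds_len = s$total_cds_len, density = s$density)
  write.table(df, summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(sites_path, summary_path))
}
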