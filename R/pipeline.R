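default_config <- function() {
  list(
    min_repeat_len = 100L, min_repeat_identity = 0.90, seed_k = 21L,
    min_anchor_len = 25L, max_gap = 5000L, min_block = 1000L,
    junction_window = 100L, max_events = 4L
  )
}

#' Read a pipeline configuration file (YAML)
#'
#' Keys mirror the CLI flags; unknown keys are rejected. Missing keys
#' take the defaults that reproduce the study-case analysis.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_config(cfg)
}

merge_config <- function(cfg) {
  base <- default_config()
  if (is.null(cfg)) return(base)
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  base[names(cfg)] <- cfg
  base
}

#' Compare two genomes: repeats, blocks, junctions, scenarios
#'
#' The full comparative analysis: repeat pairs are detected on genome B
#' (the putatively rearranged, observed genome); anchors are found
#' between the pair and chained into collinear blocks; the observed
#' block order is encoded as a signed permutation; repeat copies are
#' associated with block junctions; and a search for minimal
#' repeat-mediated inversion scenarios explaining the observed order is
#' run using placements read off the junction associations. Because
#' placements are observed in genome B, the constrained search runs from
#' the observed permutation back to the identity and the event list is
#' reversed (every inversion is its own inverse), yielding scenarios
#' oriented from the ancestral to the observed configuration.
#'
#' @param genomeA reference [annotated_genome()].
#' @param genomeB observed [annotated_genome()].
#' @param config list of settings (see [read_config()]); missing entries
#'   take defaults.
#' @return object of class `comparison_report`.
#' @export
compare_genomes <- function(genomeA, genomeB, config = list()) {
  cfg <- merge_config(config)
  repeats <- find_repeat_pairs(genomeB, min_len = cfg$min_repeat_len,
                               min_identity = cfg$min_repeat_identity,
                               k = cfg$seed_k)
  anchors <- find_anchors(genomeA, genomeB,
                          min_anchor_len = cfg$min_anchor_len)
  blocks <- chain_anchors(anchors, max_gap = cfg$max_gap,
                          min_block = cfg$min_block)
  perm <- blocks_to_permutation(blocks)
  junctions <- junction_repeat_association(blocks, repeats,
                                           window = cfg$junction_window,
                                           genome = genomeB)
  placements <- placements_from_junctions(junctions, repeats)
  n <- length(perm)
  identity_perm <- seq_len(n)
  rearranged <- !identical(perm, identity_perm)
  scenarios <- list()
  if (rearranged && nrow(placements) > 0L) {
    back <- find_repeat_mediated_scenarios(perm, identity_perm,
                                           placements,
                                           max_events = cfg$max_events)
    scenarios <- lapply(back, reverse_scenario, source = identity_perm,
                        target = perm)
  }
  structure(list(
    schema = 1L,
    genome_a = genomeA$id, genome_b = genomeB$id,
    config = cfg,
    blocks = blocks, permutation = perm,
    repeats = repeats, junctions = junctions,
    placements = placements,
    scenarios = scenarios,
    rearranged = rearranged,
    model_matched = rearranged && length(scenarios) > 0L
  ), class = "comparison_report")
}

# placements (in the observed configuration) for every repeat pair whose
# two copies sit at two distinct block junctions
placements_from_junctions <- function(junctions, repeats) {
  empty <- repeat_placement(character(0), integer(0), integer(0),
                            character(0))
  j <- junctions[!is.na(junctions$repeat_label), , drop = FALSE]
  if (nrow(j) == 0L) return(empty)
  out <- list()
  for (lab in unique(j$repeat_label)) {
    ji <- sort(unique(j$junction_index[j$repeat_label == lab]))
    if (length(ji) != 2L) next
    orient <- repeats$orientation[repeats$label == lab][1]
    out[[length(out) + 1L]] <-
      repeat_placement(lab, ji[1], ji[2], orient)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# turn a target->identity scenario into an identity->target one: the
# same inversions, applied in reverse order
reverse_scenario <- function(scenario, source, target) {
  events <- rev(scenario$events)
  perm <- source
  inter <- list()
  for (e in events) {
    perm <- apply_inversion(perm, e$segment[1], e$segment[2])
    inter[[length(inter) + 1L]] <- perm
  }
  stopifnot(identical(perm, as.integer(target)))
  list(events = events, source = as.integer(source),
       target = as.integer(target), intermediates = inter)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s\n", x$genome_a, x$genome_b))
  cat(sprintf("  blocks: %d; permutation: (%s); rearranged: %s\n",
              nrow(x$blocks), paste(x$permutation, collapse = ", "),
              if (x$rearranged) "yes" else "no"))
  cat(sprintf("  repeats >= %d bp: %d; minimal scenarios: %d\n",
              x$config$min_repeat_len, nrow(x$repeats),
              length(x$scenarios)))
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' Deterministic serialization (schema 1): identical inputs and
#' configuration produce byte-identical files.
#'
#' @param report a `comparison_report`.
#' @param path output JSON file.
#' @export
write_report_json <- function(report, path) {
  r <- unclass(report)
  r$repeats$mismatch_positions <- NULL
  r$repeats$identity <- round(r$repeats$identity, 6)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE, na = "null")
  invisible(path)
}
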