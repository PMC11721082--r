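#' Build an AAI reference database
#'
#' @param proteins An `AAStringSet` (or named character vector) of
#'   reference proteins, or a path to a protein FASTA.
#' @param taxonomy `data.frame` with columns `genome_id`, `order`,
#'   `family`, `genus`.
#' @param id_pattern Regex stripped from protein ids to recover the
#'   genome id (default: trailing `_<n>`).
#' @return Object of class `aai_reference`.
#' @export
aai_reference_db <- function(proteins, taxonomy, id_pattern = "_[^_]*$") {
  if (is.character(proteins) && length(proteins) == 1 &&
      file.exists(proteins)) {
    proteins <- Biostrings::readAAStringSet(proteins)
  }
  if (!methods::is(proteins, "AAStringSet")) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  names(proteins) <- sub("\\s.*$", "", names(proteins))
  genome_of <- sub(id_pattern, "", names(proteins))
  unknown <- setdiff(unique(genome_of), taxonomy$genome_id)
  if (length(unknown) > 0) {
    stopf("reference proteins of genomes missing from taxonomy: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(list(proteins = proteins, genome_of = genome_of,
                 taxonomy = taxonomy),
            class = "aai_reference")
}

#' @export
print.aai_reference <- function(x, ...) {
  cat(sprintf("<aai_reference> %d proteins from %d genomes\n",
              length(x$proteins), length(unique(x$genome_of))))
  invisible(x)
}

as_protein_set <- function(query) {
  if (methods::is(query, "AAStringSet")) return(query)
  Biostrings::AAStringSet(query)
}

#' One-way protein search of a query proteome against a reference
#'
#' Aligns every query protein against every reference protein with
#' local (Smith-Waterman) alignment under BLOSUM62 and affine gap
#' penalties, and keeps the best-scoring hit per (query protein,
#' reference genome). Hits below `min_score` are discarded so that
#' chance local alignments between unrelated proteins do not count as
#' homologs.
#'
#' @param query Named `AAStringSet` or character vector: the query
#'   genome's proteins.
#' @param ref An [aai_reference_db()].
#' @param min_score Minimum alignment score for a hit to qualify,
#'   default 60.
#' @param gap_opening,gap_extension Affine gap penalties (10 / 1).
#' @return `data.frame`: `query_protein_id`, `ref_protein_id`,
#'   `ref_genome_id`, `percent_identity`, `alignment_length`, `score`.
#' @export
one_way_search <- function(query, ref, min_score = 60,
                           gap_opening = 10, gap_extension = 1) {
  query <- as_protein_set(query)
  empty <- data.frame(query_protein_id = character(),
                      ref_protein_id = character(),
                      ref_genome_id = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(query) == 0) return(empty)
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  blosum62 <- get("BLOSUM62", envir = data_env)

  rows <- list()
  for (qi in seq_along(query)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(query[qi], length(ref$proteins)), ref$proteins,
      type = "local", substitutionMatrix = blosum62,
      gapOpening = gap_opening, gapExtension = gap_extension)
    sc <- Biostrings::score(aln)
    # best hit per reference genome, by score
    for (g in unique(ref$genome_of)) {
      idx <- which(ref$genome_of == g)
      best <- idx[which.max(sc[idx])]
      if (sc[best] >= min_score) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_protein_id = names(query)[qi],
          ref_protein_id = names(ref$proteins)[best],
          ref_genome_id = g,
          percent_identity = Biostrings::pid(aln[best]),
          alignment_length = Biostrings::nchar(aln[best]),
          score = sc[best], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Average amino acid identity against one reference genome
#'
#' AAI is the mean percent identity of the best hits of the query's
#' proteins against the reference genome. The alignment fraction AF is
#' the percentage of query proteins with a qualifying hit; a genome
#' pair with AF below `af_floor` is reported as AAI 0 to avoid
#' spuriously high identities from partial matches (the raw mean is
#' retained in `aai_raw`).
#'
#' @param hits Hit table from [one_way_search()].
#' @param query The query proteins (for the AF denominator).
#' @param ref_genome_id Reference genome to score against.
#' @param af_floor AF threshold in percent, default 20.
#' @return One-row `data.frame`: `query_n_proteins`, `n_hits`, `af`,
#'   `aai` (floored), `aai_raw`.
#' @export
compute_aai <- function(hits, query, ref_genome_id, af_floor = 20) {
  query <- as_protein_set(query)
  if (length(query) == 0) stopf("empty query protein set")
  h <- hits[hits$ref_genome_id == ref_genome_id, , drop = FALSE]
  # one best hit per query protein
  if (nrow(h) > 1) {
    h <- h[order(h$query_protein_id, -h$score), , drop = FALSE]
    h <- h[!duplicated(h$query_protein_id), , drop = FALSE]
  }
  af <- 100 * nrow(h) / length(query)
  aai_raw <- if (nrow(h) > 0) mean(h$percent_identity) else 0
  data.frame(
    query_n_proteins = length(query), n_hits = nrow(h),
    af = af,
    aai = if (af < af_floor) 0 else aai_raw,
    aai_raw = aai_raw, stringsAsFactors = FALSE)
}

#' Best reference match of a query proteome
#'
#' Scores the query against every reference genome and returns the
#' match maximizing the (floored) AAI; ties are broken by higher AF,
#' then lexicographic genome id. When no reference clears the AF
#' floor the best match is `NA` with AAI 0.
#'
#' @inheritParams one_way_search
#' @inheritParams compute_aai
#' @return Object of class `aai_result`: one-row `data.frame` with
#'   `best_match_genome_id`, `aai`, `af`, `order`, `family`, `genus`
#'   plus the full per-reference table in `attr(, "all_matches")`.
#' @export
aai_best_match <- function(query, ref, af_floor = 20, min_score = 60) {
  query <- as_protein_set(query)
  hits <- one_way_search(query, ref, min_score = min_score)
  genomes <- sort(unique(ref$genome_of))
  per_ref <- do.call(rbind, lapply(genomes, function(g) {
    cbind(ref_genome_id = g,
          compute_aai(hits, query, g, af_floor = af_floor))
  }))
  passing <- per_ref[per_ref$aai > 0, , drop = FALSE]
  if (nrow(passing) == 0) {
    out <- data.frame(best_match_genome_id = NA_character_,
                      aai = 0, af = 0,
                      order = NA_character_, family = NA_character_,
                      genus = NA_character_, stringsAsFactors = FALSE)
  } else {
    best <- passing[order(-passing$aai, -passing$af,
                          passing$ref_genome_id), , drop = FALSE][1, ]
    tax <- ref$taxonomy[match(best$ref_genome_id, ref$taxonomy$genome_id), ]
    out <- data.frame(best_match_genome_id = best$ref_genome_id,
                      aai = best$aai, af = best$af,
                      order = tax$order, family = tax$family,
                      genus = tax$genus, stringsAsFactors = FALSE)
  }
  structure(out, class = c("aai_result", "data.frame"),
            all_matches = per_ref)
}

#' @export
print.aai_result <- function(x, ...) {
  if (is.na(x$best_match_genome_id)) {
    cat("<aai_result> no reference genome above the AF floor (AAI = 0)\n")
  } else {
    cat(sprintf("<aai_result> best match %s: AAI %.1f%%, AF %.1f%% (%s / %s / %s)\n",
                x$best_match_genome_id, x$aai, x$af,
                x$order, x$family, x$genus))
  }
  invisible(x)
}
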