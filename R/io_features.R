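#' Construct a genome record
#'
#' A genome record bundles the contigs of one (possibly multi-contig)
#' genome assembly. Metagenome-assembled genomes are typically
#' multi-contig; isolate genomes are often a single contig.
#'
#' @param genome_id Character scalar, unique genome identifier.
#' @param contigs Named character vector of nucleotide sequences
#'   (names are contig ids, unique within the genome).
#' @return An object of class `genome_record` with fields `genome_id`,
#'   `contigs` and `total_length`.
#' @export
genome_record <- function(genome_id, contigs) {
  if (!is.character(contigs) || length(contigs) == 0) {
    stopf("genome '%s': contigs must be a non-empty named character vector",
          genome_id)
  }
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == "")) {
    stopf("genome '%s': every contig needs a name", genome_id)
  }
  if (anyDuplicated(names(contigs))) {
    stopf("genome '%s': duplicate contig id '%s'", genome_id,
          names(contigs)[duplicated(names(contigs))][1])
  }
  if (any(nchar(contigs) == 0)) {
    stopf("genome '%s': empty contig sequence '%s'", genome_id,
          names(contigs)[nchar(contigs) == 0][1])
  }
  structure(
    list(genome_id = genome_id, contigs = contigs,
         total_length = sum(nchar(contigs))),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %s bp\n",
              x$genome_id, length(x$contigs),
              format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Read genomes from nucleotide FASTA
#'
#' @param path Path to a FASTA file (optionally gzipped), or a directory
#'   of FASTA files when `grouping` is `"per_file"`.
#' @param grouping How records map to genomes: `"per_file"` (all records
#'   in one file form one genome, named after the file), `"per_record"`
#'   (each record is a single-contig genome) or `"id_prefix"` (records
#'   sharing the prefix before the last `_` belong to one genome).
#' @return Named list of [genome_record()] objects.
#' @export
read_genomes <- function(path, grouping = c("per_file", "per_record", "id_prefix")) {
  grouping <- match.arg(grouping)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fna|fasta)(\\.gz)?$",
                        full.names = TRUE)
    out <- list()
    for (f in files) out <- c(out, read_genomes(f, grouping))
    if (anyDuplicated(names(out))) {
      stopf("duplicate genome id across files: '%s'",
            names(out)[duplicated(names(out))][1])
    }
    return(out)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    warnf("no sequences in '%s'", path)
    return(list())
  }
  ids <- sub("\\s.*$", "", names(seqs))
  contigs <- as.character(seqs)
  names(contigs) <- ids
  genomes <- switch(grouping,
    per_file = {
      gid <- sub("\\.(fa|fna|fasta)(\\.gz)?$", "", basename(path))
      list(genome_record(gid, contigs))
    },
    per_record = lapply(seq_along(contigs), function(i) {
      genome_record(ids[i], contigs[i])
    }),
    id_prefix = {
      gids <- sub("_[^_]*$", "", ids)
      lapply(unique(gids), function(g) {
        genome_record(g, contigs[gids == g])
      })
    }
  )
  names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  if (anyDuplicated(names(genomes))) {
    stopf("duplicate genome id '%s' in '%s'",
          names(genomes)[duplicated(names(genomes))][1], path)
  }
  genomes
}

#' GC content of a genome
#'
#' Computed over the concatenation of all contigs (length-weighted), as
#' (G+C)/(A+C+G+T), case-insensitive. `N` and other ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param genome A [genome_record()], or a character vector of
#'   nucleotide sequences.
#' @return Fraction in \[0, 1\].
#' @export
compute_gc <- function(genome) {
  seqs <- if (inherits(genome, "genome_record")) genome$contigs else genome
  dna <- Biostrings::DNAStringSet(toupper(seqs))
  counts <- colSums(Biostrings::letterFrequency(dna, c("A", "C", "G", "T")))
  denom <- sum(counts)
  if (denom == 0) stopf("no unambiguous bases (A/C/G/T) in sequence")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' Parse HMMER3 per-target tabular output (tblout)
#'
#' Reads `hmmsearch --tblout` output and keeps hits whose full-sequence
#' E-value is at or below the threshold. The full-sequence E-value
#' (column 5) is hmmsearch's primary significance measure.
#'
#' @param path Path to a tblout file, or a character vector of lines.
#' @param evalue_threshold Inclusive E-value cutoff. Default `1e-10`.
#' @return `data.frame` with columns `protein_id`, `gvog_id`, `evalue`,
#'   `score`, one row per retained hit.
#' @export
parse_hmm_hits <- function(path, evalue_threshold = 1e-10) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  keep <- !grepl("^\\s*(#|$)", lines)
  data_idx <- which(keep)
  empty <- data.frame(protein_id = character(), gvog_id = character(),
                      evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(data_idx) == 0) return(empty)
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stopf("tblout parse error at line %d: expected >= 6 whitespace-delimited fields, got %d",
          data_idx[which(nf < 6)[1]], min(nf))
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  if (anyNA(ev)) {
    stopf("tblout parse error at line %d: non-numeric E-value field '%s'",
          data_idx[which(is.na(ev))[1]],
          vapply(fields, `[`, "", 5L)[which(is.na(ev))[1]])
  }
  sc <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 6L)))
  hits <- data.frame(
    protein_id = vapply(fields, `[`, "", 1L),
    gvog_id = vapply(fields, `[`, "", 3L),
    evalue = ev,
    score = sc,
    stringsAsFactors = FALSE
  )
  hits[hits$evalue <= evalue_threshold, , drop = FALSE]
}

# Map protein ids to genome ids. Default follows Prodigal's
# "<contig>_<n>" convention: strip the trailing "_<n>" to recover the
# contig, then look the contig up in the supplied genomes; ids that
# already name a genome after stripping are accepted too.
map_proteins_to_genomes <- function(protein_ids, genomes,
                                    id_pattern = "_[^_]*$") {
  contig2genome <- do.call(c, unname(lapply(genomes, function(g) {
    stats::setNames(rep(g$genome_id, length(g$contigs)), names(g$contigs))
  })))
  stripped <- sub(id_pattern, "", protein_ids)
  out <- unname(contig2genome[stripped])
  direct <- stripped %in% names(genomes)
  out[is.na(out) & direct] <- stripped[is.na(out) & direct]
  out
}

#' Build the genome-by-feature matrix
#'
#' Rows are genomes; the first column is GC content, remaining columns
#' are binary GVOG presence (1 if any protein of the genome has a
#' retained hit against that GVOG). Presence, not counts: hit
#' multiplicity carries completeness bias and is deliberately ignored.
#' Genome size is never a feature.
#'
#' @param genomes Named list of [genome_record()] objects.
#' @param hits Hit table from [parse_hmm_hits()].
#' @param gvog_ids Ordered character vector fixing the GVOG column set.
#' @param id_pattern Regex stripped from protein ids to recover the
#'   contig/genome id (default: Prodigal's trailing `_<n>`).
#' @return Numeric matrix with rownames = genome ids and colnames =
#'   `c("gc_content", gvog_ids)`.
#' @export
build_feature_matrix <- function(genomes, hits, gvog_ids,
                                 id_pattern = "_[^_]*$") {
  if (anyDuplicated(gvog_ids)) stopf("gvog_ids contains duplicates")
  gids <- unname(vapply(genomes, `[[`, "", "genome_id"))
  mat <- matrix(0, nrow = length(genomes), ncol = 1 + length(gvog_ids),
                dimnames = list(gids, c("gc_content", gvog_ids)))
  mat[, "gc_content"] <- vapply(genomes, compute_gc, 0)
  if (nrow(hits) > 0) {
    hit_genome <- map_proteins_to_genomes(hits$protein_id, genomes, id_pattern)
    if (anyNA(hit_genome)) {
      orphans <- unique(hits$protein_id[is.na(hit_genome)])
      stopf("hits reference proteins of unknown genomes: %s",
            paste(utils::head(orphans, 5), collapse = ", "))
    }
    keep <- hits$gvog_id %in% gvog_ids
    if (any(keep)) {
      mat[cbind(hit_genome[keep], hits$gvog_id[keep])] <- 1
    }
  }
  mat
}

#' Write / read a feature matrix as TSV with a JSON sidecar
#'
#' The TSV has one row per genome (first column `genome_id`); the
#' sidecar records the feature order so column order round-trips
#' bit-exactly.
#'
#' @param mat Feature matrix from [build_feature_matrix()].
#' @param path Output TSV path; the sidecar is written to
#'   `<path>.json`.
#' @param meta Optional named list merged into the sidecar (e.g. the
#'   E-value threshold used).
#' @export
write_feature_matrix <- function(mat, path, meta = list()) {
  df <- data.frame(genome_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- c(list(feature_names = colnames(mat)), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$genome_id
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    mat <- mat[, sidecar$feature_names, drop = FALSE]
  }
  mat
}
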