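# Label-structured synthetic data: mock genomes, hit tables and labels
# with per-class GVOG signatures and GC offsets, so the whole pipeline
# is testable end-to-end without external databases or binaries.

#' Build per-class GVOG signatures
#'
#' Emulates the block structure of real giant-virus lineages: each
#' order owns a core set of signature GVOGs shared by all its
#' families, and each family adds a smaller family-specific set,
#' disjoint across families. A member genome carries each of its
#' signature GVOGs with probability `p_signature` and any other GVOG
#' with probability `p_background`. Classes also differ in GC content.
#'
#' @param n_orders Number of order-level classes (the last one plays
#'   the non-giant-virus role when `order_names` is default).
#' @param families_per_order Families per order.
#' @param gvogs_total Size of the GVOG pool; must cover the total
#'   signature demand.
#' @param core_size,family_size Signature GVOGs per order core / per
#'   family-specific addition.
#' @param p_signature,p_background Presence probabilities.
#' @param gc_range Range over which order GC means are spread.
#' @param gc_sd Per-genome GC standard deviation.
#' @param order_names Optional order names (default: real giant-virus
#'   orders, then `incertae_sedis` and `Not_GV`, then synthetic names).
#' @param seed Integer seed.
#' @return List of class `gv_signatures`; one element per family
#'   class, each with `order`, `family`, `signature`, `p_signature`,
#'   `p_background`, `gc_mean`, `gc_sd`. Attributes: `gvog_ids`,
#'   `orders`, `families`.
#' @export
make_signatures <- function(n_orders = 8, families_per_order = 2,
                            gvogs_total = 600, core_size = 30,
                            family_size = 10, p_signature = 0.9,
                            p_background = 0.02,
                            gc_range = c(0.25, 0.55), gc_sd = 0.02,
                            order_names = NULL, seed = 1L) {
  stopifnot(p_background < p_signature, p_signature <= 1, p_background >= 0)
  demand <- n_orders * (core_size + families_per_order * family_size)
  if (gvogs_total < demand) {
    stopf("gvog pool (%d) smaller than signature demand (%d)",
          gvogs_total, demand)
  }
  default_orders <- c("Algavirales", "Asfuvirales", "Chitovirales",
                      "Imitervirales", "Pandoravirales", "Pimascovirales",
                      "incertae_sedis", "Not_GV")
  if (is.null(order_names)) {
    order_names <- c(default_orders,
                     sprintf("Order%02d", seq_len(max(0, n_orders - 8))))
  }
  order_names <- order_names[seq_len(n_orders)]
  gvog_ids <- sprintf("GVOG%04d", seq_len(gvogs_total))

  with_seed(seed, {
    pool <- sample(gvog_ids)   # shuffled so signatures are scattered ids
    gc_means <- seq(gc_range[1], gc_range[2], length.out = n_orders)
    gc_means <- gc_means[sample.int(n_orders)]
    sigs <- list()
    take <- function(n) {
      out <- pool[seq_len(n)]
      pool <<- pool[-seq_len(n)]
      out
    }
    for (o in seq_len(n_orders)) {
      core <- take(core_size)
      for (f in seq_len(families_per_order)) {
        fam_label <- sprintf("%s_%02d", toupper(substr(order_names[o], 1, 2)), f)
        sigs[[length(sigs) + 1L]] <- list(
          order = order_names[o],
          family = fam_label,
          signature = sort(c(core, take(family_size))),
          p_signature = p_signature,
          p_background = p_background,
          gc_mean = gc_means[o],
          gc_sd = gc_sd
        )
      }
    }
    structure(sigs, class = "gv_signatures", gvog_ids = gvog_ids,
              orders = order_names,
              families = vapply(sigs, `[[`, "", "family"))
  })
}

#' @export
print.gv_signatures <- function(x, ...) {
  cat(sprintf("<gv_signatures> %d family classes in %d orders, pool of %d GVOGs\n",
              length(x), length(unique(attr(x, "orders"))),
              length(attr(x, "gvog_ids"))))
  invisible(x)
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Sample a synthetic labeled dataset
#'
#' Draws genomes class by class: GVOG presence is Bernoulli per the
#' class signature; each present GVOG is materialized as a
#' protein-coding locus at a random genome coordinate and a
#' significant tblout hit line (E-value well below 1e-10). A fraction
#' of absent GVOGs is emitted as decoy lines with E-values above the
#' threshold so the E-value filter is genuinely exercised. Contig
#' sequences are drawn at the genome's GC.
#'
#' Because each hit is anchored to a genome coordinate, fragmenting a
#' genome (see [fragmentize_dataset()]) genuinely removes the hits
#' whose loci fall outside the retained windows, so completeness
#' degrades feature presence the way it does for real incomplete MAGs.
#'
#' @param signatures A [make_signatures()] result.
#' @param genomes_per_class Genomes drawn per family class.
#' @param genome_length Approximate genome length in bp.
#' @param n_contigs Contigs per genome.
#' @param locus_length Footprint of one protein locus in bp.
#' @param decoy_rate Fraction of absent GVOGs emitted as
#'   above-threshold decoy hits.
#' @param seed Integer seed; regeneration is deterministic.
#' @return Object of class `gv_synthetic`: `genomes`, `tblout`
#'   (character lines), `labels` (`genome_id`, `order`, `family`,
#'   `group`), `presence` (the generator's internal genome x GVOG
#'   presence matrix), `proteins` (locus coordinates), `gvog_ids`,
#'   `params`.
#' @export
sample_dataset <- function(signatures, genomes_per_class = 50,
                           genome_length = 20000, n_contigs = 4,
                           locus_length = 900, decoy_rate = 0.01,
                           seed = 1L) {
  stopifnot(genomes_per_class >= 1)
  gvog_ids <- attr(signatures, "gvog_ids")
  genomes <- list()
  labels <- list()
  tbl_lines <- list(
    "#                                                               --- full sequence ---",
    "# target name        accession  query name           accession    E-value  score  bias")
  presence <- list()
  prot_rows <- list()

  with_seed(seed, {
    for (sig in signatures) {
      for (i in seq_len(genomes_per_class)) {
        gid <- sprintf("%s_g%03d", sig$family, i)
        p <- ifelse(gvog_ids %in% sig$signature, sig$p_signature,
                    sig$p_background)
        present <- gvog_ids[stats::runif(length(gvog_ids)) < p]
        gc <- min(0.8, max(0.2, stats::rnorm(1, sig$gc_mean, sig$gc_sd)))

        clen <- rep(genome_length %/% n_contigs, n_contigs)
        contigs <- vapply(clen, random_dna, "", gc = gc)
        names(contigs) <- sprintf("%s_c%d", gid, seq_len(n_contigs))
        genomes[[gid]] <- genome_record(gid, contigs)

        # one protein locus per present GVOG, anchored to a coordinate
        n_per_contig <- integer(n_contigs)
        if (length(present) > 0) {
          ci <- sample.int(n_contigs, length(present), replace = TRUE)
          pnum <- stats::ave(ci, ci, FUN = seq_along)
          start <- vapply(ci, function(k) {
            sample.int(max(1L, clen[k] - locus_length + 1L), 1L)
          }, 0L)
          pid <- sprintf("%s_%d", names(contigs)[ci], pnum)
          prot_rows[[length(prot_rows) + 1L]] <- data.frame(
            protein_id = pid, genome_id = gid,
            contig_id = names(contigs)[ci],
            start = start,
            end = pmin(clen[ci], start + locus_length - 1L),
            gvog_id = present, stringsAsFactors = FALSE)
          n_per_contig <- tabulate(ci, n_contigs)
          tbl_lines[[length(tbl_lines) + 1L]] <- sprintf(
            "%-20s -          %-12s -          %9.2g  %5.1f   0.0",
            pid, present, 10^-stats::runif(length(present), 12, 40),
            60 + stats::runif(length(present), 0, 200))
        }
        # decoys: absent GVOGs with non-significant E-values
        absent <- setdiff(gvog_ids, present)
        decoys <- absent[stats::runif(length(absent)) < decoy_rate]
        if (length(decoys) > 0) {
          ci <- sample.int(n_contigs, length(decoys), replace = TRUE)
          pnum <- n_per_contig[ci] + stats::ave(ci, ci, FUN = seq_along)
          pid <- sprintf("%s_%d", names(contigs)[ci], pnum)
          tbl_lines[[length(tbl_lines) + 1L]] <- sprintf(
            "%-20s -          %-12s -          %9.2g  %5.1f   0.0",
            pid, decoys, 10^-stats::runif(length(decoys), 0, 9),
            stats::runif(length(decoys), 5, 20))
        }
        presence[[gid]] <- as.integer(gvog_ids %in% present)
        labels[[gid]] <- data.frame(
          genome_id = gid, order = sig$order, family = sig$family,
          group = if (sig$order == "Not_GV") "Not_GV" else sig$order,
          stringsAsFactors = FALSE)
      }
    }
  })
  pres <- do.call(rbind, presence)
  colnames(pres) <- gvog_ids
  structure(list(
    genomes = genomes,
    tblout = unlist(tbl_lines),
    labels = do.call(rbind, c(labels, list(make.row.names = FALSE))),
    presence = pres,
    proteins = do.call(rbind, prot_rows),
    gvog_ids = gvog_ids,
    params = list(genomes_per_class = genomes_per_class,
                  genome_length = genome_length, n_contigs = n_contigs,
                  locus_length = locus_length, decoy_rate = decoy_rate,
                  seed = seed)
  ), class = "gv_synthetic")
}

#' @export
print.gv_synthetic <- function(x, ...) {
  cat(sprintf("<gv_synthetic> %d genomes, %d family classes, %d orders, %d GVOGs\n",
              length(x$genomes), length(unique(x$labels$family)),
              length(unique(x$labels$order)), length(x$gvog_ids)))
  invisible(x)
}

#' Feature matrix of a synthetic dataset
#'
#' Runs the real featurization path (tblout parsing with the E-value
#' filter, GC computation) on the generated fixtures.
#'
#' @param ds A [sample_dataset()] result.
#' @param evalue_threshold Passed to [parse_hmm_hits()].
#' @export
synthetic_feature_matrix <- function(ds, evalue_threshold = 1e-10) {
  hits <- parse_hmm_hits(ds$tblout, evalue_threshold)
  build_feature_matrix(ds$genomes, hits, ds$gvog_ids)
}

#' Fragment every genome of a synthetic dataset
#'
#' Each genome is fragmented to the given completeness; a hit survives
#' only when its protein locus lies entirely inside a retained window,
#' so lower completeness genuinely removes features.
#'
#' @param ds A [sample_dataset()] result.
#' @param completeness Target completeness for every genome.
#' @param seed Integer seed.
#' @return List: `genomes` (fragments, ids `<source>_frag01`), `hits`
#'   (surviving hits as a [parse_hmm_hits()]-shaped table), `labels`
#'   (inherited from sources).
#' @export
fragmentize_dataset <- function(ds, completeness, seed = 1L) {
  frags <- list()
  hit_rows <- list()
  labels <- list()
  for (i in seq_along(ds$genomes)) {
    g <- ds$genomes[[i]]
    frag <- fragmentize(g, completeness, seed = child_seed(seed, i),
                        fragment_id = paste0(g$genome_id, "_frag01"))
    frags[[frag$genome_id]] <- frag
    ranges <- attr(frag, "source_ranges")
    prot <- ds$proteins[ds$proteins$genome_id == g$genome_id, , drop = FALSE]
    if (nrow(prot) > 0) {
      m <- match(prot$contig_id, ranges$source_contig)
      survives <- !is.na(m) & prot$start >= ranges$start[m] &
        prot$end <= ranges$end[m]
      if (any(survives)) {
        kept <- prot[survives, , drop = FALSE]
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          # re-anchor protein ids onto the fragment's contigs
          protein_id = paste0(ranges$contig_id[m[survives]], "_x"),
          gvog_id = kept$gvog_id,
          evalue = 1e-20, score = 100, stringsAsFactors = FALSE)
      }
    }
    lab <- ds$labels[ds$labels$genome_id == g$genome_id, , drop = FALSE]
    lab$genome_id <- frag$genome_id
    labels[[length(labels) + 1L]] <- lab
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(protein_id = character(), gvog_id = character(),
               evalue = numeric(), score = numeric())
  list(genomes = frags, hits = hits,
       labels = do.call(rbind, c(labels, list(make.row.names = FALSE))))
}

#' The default study-scale synthetic benchmark
#'
#' Eight order-level classes (seven giant-virus orders plus a
#' non-giant-virus class), two families per order (16 family-level
#' classes), 100 genomes per order, presence probabilities 0.9 inside
#' and 0.02 outside the class signature, from a pool of 600 GVOGs.
#'
#' @param seed Integer seed.
#' @param genomes_per_order Genomes per order class (split evenly over
#'   its families), default 100.
#' @export
paper_like_dataset <- function(seed = 1L, genomes_per_order = 100) {
  sigs <- make_signatures(n_orders = 8, families_per_order = 2,
                          gvogs_total = 600, core_size = 30,
                          family_size = 10, p_signature = 0.9,
                          p_background = 0.02, seed = seed)
  sample_dataset(sigs, genomes_per_class = genomes_per_order %/% 2,
                 seed = child_seed(seed, 99))
}

#' Write a synthetic dataset as plain-text fixtures
#'
#' Emits one nucleotide FASTA per genome under `genomes/`, the hit
#' table as `hits.tblout`, labels as `labels.tsv`, the GVOG list and a
#' manifest JSON.
#'
#' @param ds A [sample_dataset()] result.
#' @param dir Output directory.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  for (g in ds$genomes) {
    writeLines(
      as.vector(rbind(paste0(">", names(g$contigs)), unname(g$contigs))),
      file.path(gdir, paste0(g$genome_id, ".fna")))
  }
  writeLines(ds$tblout, file.path(dir, "hits.tblout"))
  utils::write.table(ds$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(ds$gvog_ids, file.path(dir, "gvogs.txt"))
  jsonlite::write_json(ds$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Random toy proteomes for AAI testing
#'
#' @param n Number of proteins.
#' @param length_range Protein lengths are drawn uniformly from this
#'   range.
#' @param seed Integer seed.
#' @return Named character vector of amino-acid sequences.
#' @export
random_proteins <- function(n, length_range = c(60, 120), seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    stats::setNames(
      vapply(lens, function(l) paste(sample(aa, l, replace = TRUE),
                                     collapse = ""), ""),
      sprintf("prot_%03d", seq_len(n)))
  })
}

#' Point-mutate a proteome at a fixed per-residue rate
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param rate Per-residue substitution probability.
#' @param seed Integer seed.
#' @export
mutate_proteome <- function(proteins, rate, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    out <- vapply(proteins, function(p) {
      chars <- strsplit(p, "")[[1]]
      hit <- stats::runif(length(chars)) < rate
      if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(orig) {
          sample(setdiff(aa, orig), 1L)
        }, "")
      }
      paste(chars, collapse = "")
    }, "")
    names(out) <- names(proteins)
    out
  })
}
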