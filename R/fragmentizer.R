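#' Simulate an incomplete genome fragment
#'
#' Produces a fragmented variant of a genome at a given completeness
#' (fragment length / source length). For a single-contig genome one
#' contiguous window of the target length is taken at a uniformly
#' random start. For multi-contig genomes the contigs are shuffled,
#' whole contigs are accumulated until the next would exceed the
#' target, and the final contig is trimmed (uniform window) to hit the
#' target exactly — mimicking how genome binning loses whole contigs
#' while preserving local contiguity.
#'
#' @param genome A [genome_record()].
#' @param completeness Target completeness, in (0, 1].
#' @param seed Integer seed; the result is deterministic given
#'   `(genome, completeness, seed)`.
#' @param fragment_id Id for the fragment genome; default
#'   `<source>_frag<seed>`.
#' @return A [genome_record()] whose contigs are exact substrings of
#'   source contigs. Attributes: `source_genome_id`,
#'   `target_completeness`, `achieved_completeness`, and
#'   `source_ranges`, a data.frame (`source_contig`, `start`, `end`,
#'   1-based inclusive) locating each fragment contig in its source.
#' @export
fragmentize <- function(genome, completeness, seed = NULL,
                        fragment_id = NULL) {
  if (!is.numeric(completeness) || length(completeness) != 1 ||
      completeness <= 0 || completeness > 1) {
    stopf("completeness must be in (0, 1], got %s",
          format(completeness))
  }
  fragment_id <- fragment_id %||%
    sprintf("%s_frag%s", genome$genome_id, seed %||% "0")
  target <- max(1L, as.integer(round(completeness * genome$total_length)))

  with_seed(seed, {
    ord <- if (length(genome$contigs) > 1) {
      sample.int(length(genome$contigs))
    } else 1L
    kept <- character(0)
    ranges <- list()
    remaining <- target
    for (i in ord) {
      len <- nchar(genome$contigs[[i]])
      cid <- names(genome$contigs)[i]
      if (len <= remaining) {
        kept[cid] <- genome$contigs[[i]]
        ranges[[cid]] <- c(1L, len)
        remaining <- remaining - len
        if (remaining == 0) break
      } else {
        # trim the final contig with a uniformly placed window
        start <- sample.int(len - remaining + 1L, 1L)
        kept[paste0(cid, "|", start, "-", start + remaining - 1L)] <-
          substr(genome$contigs[[i]], start, start + remaining - 1L)
        ranges[[paste0(cid, "|", start, "-", start + remaining - 1L)]] <-
          c(start, start + remaining - 1L)
        remaining <- 0L
        break
      }
    }
    frag <- genome_record(fragment_id, kept)
    src <- vapply(strsplit(names(kept), "\\|"), `[`, "", 1L)
    attr(frag, "source_genome_id") <- genome$genome_id
    attr(frag, "target_completeness") <- completeness
    attr(frag, "achieved_completeness") <- frag$total_length / genome$total_length
    attr(frag, "source_ranges") <- data.frame(
      contig_id = names(kept),
      source_contig = src,
      start = vapply(ranges, `[`, 0L, 1L),
      end = vapply(ranges, `[`, 0L, 2L),
      row.names = NULL, stringsAsFactors = FALSE
    )
    frag
  })
}

#' Fragmentation/augmentation policy
#'
#' A policy is a set of additive rules. Every rule whose `groups`
#' selector matches a genome's group label contributes
#' `n_fragments` fragments with completeness drawn uniformly from
#' `[c_low, c_high]`; a genome matching several rules receives the sum
#' of their fragments.
#'
#' @param rules List of rules created by [policy_rule()].
#' @param include_originals Keep the unfragmented genomes in the
#'   augmented output (default `TRUE`).
#' @export
augmentation_policy <- function(rules, include_originals = TRUE) {
  structure(list(rules = rules, include_originals = include_originals),
            class = "augmentation_policy")
}

#' @rdname augmentation_policy
#' @param groups Character vector of group labels the rule applies to,
#'   or `"*"` for all genomes.
#' @param n_fragments Fragments per matching genome (>= 0).
#' @param c_low,c_high Completeness sampling bounds, 0 < low <= high <= 1.
#' @export
policy_rule <- function(groups, n_fragments, c_low, c_high) {
  stopifnot(n_fragments >= 0, c_low > 0, c_low <= c_high, c_high <= 1)
  list(groups = groups, n_fragments = as.integer(n_fragments),
       c_low = c_low, c_high = c_high)
}

#' The default training-set augmentation policy
#'
#' Giant-virus genomes receive 2 fragments at completeness 23--99%;
#' non-giant-virus genomes (Mirusviricota, jumbo phages; group
#' `Not_GV`) receive 1 fragment at 29--99%; the rare Pokkesviricetes
#' *incertae sedis* genomes receive 6 additional fragments on top of
#' the giant-virus default.
#'
#' @param gv_groups Group labels counted as giant viruses.
#' @param notgv_group Label of the non-giant-virus group.
#' @param rare_group Label of the rare *incertae sedis* group (must
#'   also appear in `gv_groups` to receive the base 2 fragments).
#' @export
training_policy <- function(gv_groups, notgv_group = "Not_GV",
                            rare_group = "incertae_sedis") {
  augmentation_policy(list(
    policy_rule(gv_groups, 2L, 0.23, 0.99),
    policy_rule(notgv_group, 1L, 0.29, 0.99),
    policy_rule(rare_group, 6L, 0.23, 0.99)
  ))
}

# Fragments each genome will receive under a policy (sum over matching
# rules), given a vector of group labels named by genome id.
fragments_per_genome <- function(groups, policy) {
  counts <- integer(length(groups))
  for (rule in policy$rules) {
    m <- if (identical(rule$groups, "*")) rep(TRUE, length(groups)) else
      groups %in% rule$groups
    counts[m] <- counts[m] + rule$n_fragments
  }
  stats::setNames(counts, names(groups))
}

#' Plan an augmentation without generating sequences
#'
#' @param groups Named character vector: genome id -> group label.
#' @param policy An [augmentation_policy()].
#' @return List with `per_genome` fragment counts and `total` output
#'   sequence count (originals included when the policy keeps them).
#' @export
augment_plan <- function(groups, policy) {
  per_genome <- fragments_per_genome(groups, policy)
  total <- sum(per_genome) +
    if (policy$include_originals) length(groups) else 0L
  list(per_genome = per_genome, total = as.integer(total))
}

#' Augment a labeled genome set with fragmented variants
#'
#' @param genomes Named list of [genome_record()] objects.
#' @param labels `data.frame` with columns `genome_id`, `group` (the
#'   policy selector) and any further label columns; fragments inherit
#'   all label columns of their source.
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed; output is deterministic.
#' @return List: `genomes` (originals + fragments), `labels`
#'   (augmented, with `source_genome_id` and `completeness` columns)
#'   and `manifest` (fragment_id, source_id, target and achieved
#'   completeness, seed used).
#' @export
augment_set <- function(genomes, labels, policy, seed = 1L) {
  gids <- vapply(genomes, `[[`, "", "genome_id")
  missing_lab <- setdiff(gids, labels$genome_id)
  if (length(missing_lab) > 0) {
    stopf("unlabeled genomes: %s",
          paste(utils::head(missing_lab, 5), collapse = ", "))
  }
  groups <- stats::setNames(
    labels$group[match(gids, labels$genome_id)], gids)
  n_frag <- fragments_per_genome(groups, policy)

  # completeness bounds per fragment: fragments are assigned to rules in
  # rule order so each draw respects its own rule's bounds
  out_genomes <- if (policy$include_originals) genomes else list()
  out_rows <- if (policy$include_originals) {
    cbind(labels[match(gids, labels$genome_id), , drop = FALSE],
          source_genome_id = gids, completeness = 1)
  } else NULL
  manifest <- list()

  counter <- 0L
  for (g in gids) {
    idx <- 0L
    for (rule in policy$rules) {
      matches <- identical(rule$groups, "*") || groups[[g]] %in% rule$groups
      if (!matches || rule$n_fragments == 0) next
      for (j in seq_len(rule$n_fragments)) {
        counter <- counter + 1L
        idx <- idx + 1L
        fseed <- child_seed(seed, counter)
        comp <- with_seed(fseed, stats::runif(1, rule$c_low, rule$c_high))
        fid <- sprintf("%s_frag%02d", g, idx)
        frag <- fragmentize(genomes[[g]], comp, seed = fseed,
                            fragment_id = fid)
        out_genomes[[fid]] <- frag
        row <- labels[match(g, labels$genome_id), , drop = FALSE]
        row$genome_id <- fid
        row$source_genome_id <- g
        row$completeness <- attr(frag, "achieved_completeness")
        out_rows <- rbind(out_rows, row)
        manifest[[length(manifest) + 1L]] <- data.frame(
          fragment_id = fid, source_id = g,
          target_completeness = comp,
          achieved_completeness = attr(frag, "achieved_completeness"),
          seed = fseed, stringsAsFactors = FALSE)
      }
    }
  }
  rownames(out_rows) <- NULL
  list(genomes = out_genomes, labels = out_rows,
       manifest = if (length(manifest)) do.call(rbind, manifest) else
         data.frame(fragment_id = character(), source_id = character(),
                    target_completeness = numeric(),
                    achieved_completeness = numeric(), seed = integer()))
}
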