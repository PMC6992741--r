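# Construction of the energy-stratified training sets trA/trB/trC and the
# random baseline trR, plus permutation negatives, P/N ratio control,
# stratified folds and gene-list subsetting.

.check_interactions <- function(table) {
  need <- c("mirna_id", "target_id")
  if (!all(need %in% names(table))) stop("need columns mirna_id, target_id")
  if (anyDuplicated(paste(table$mirna_id, table$target_id, sep = "|")))
    stop("duplicate (mirna_id, target_id) pairs in interaction table")
  invisible(table)
}

#' Rank each miRNA's candidate pairs by binding energy
#'
#' Orders every miRNA's candidate targets from most stable (most negative
#' binding free energy, kcal/mol) to least stable. Energy ties are broken by
#' target id so the ranking is deterministic.
#'
#' @param table Interaction data.frame with columns `mirna_id`, `target_id`,
#'   `energy` (kcal/mol; more negative = more stable).
#' @return Named list (one element per miRNA, in miRNA id order) of
#'   data.frames sorted by ascending energy.
#' @export
rank_pairs_by_energy <- function(table) {
  .check_interactions(table)
  if (!"energy" %in% names(table)) stop("energy column required")
  miss <- which(is.na(table$energy))
  if (length(miss) > 0)
    stop("missing energy for pair (", table$mirna_id[miss[1]], ", ",
         table$target_id[miss[1]], ")")
  lst <- split(table, table$mirna_id)
  lapply(lst, function(d) d[order(d$energy, d$target_id), , drop = FALSE])
}

# Assign deterministic pick orders for one miRNA's ranked candidates.
# Returns row indices for the positive (stable) and negative (unstable)
# halves, never overlapping, each at most `per_half` long.
.pick_extremes <- function(m, per_half) {
  pos <- integer(0); neg <- integer(0)
  lo <- 1; hi <- m
  for (r in seq_len(per_half)) {
    if (lo <= hi) { pos <- c(pos, lo); lo <- lo + 1 }
    if (lo <= hi) { neg <- c(neg, hi); hi <- hi - 1 }
  }
  list(pos = pos, neg = neg)
}

#' Build a training set from an energy-annotated interaction table
#'
#' Four designs stratified on binding free energy:
#' \describe{
#'   \item{trA}{per miRNA, the most stable pair (labelled positive) and the
#'     most unstable pair (labelled negative); 2 records per miRNA.}
#'   \item{trB}{the two most stable vs the two most unstable pairs per
#'     miRNA; 4 records per miRNA.}
#'   \item{trC}{the most stable and most unstable pair per miRNA plus the
#'     two unused candidates nearest the miRNA's median energy (the more
#'     stable of the two joins the positive half); 4 records per miRNA.}
#'   \item{trR}{a uniform random sample of `size` records keeping the input
#'     labels; requires `seed`.}
#' }
#' For trA/trB/trC the positive/negative labels are a stability convention
#' on the input pairs (strong binders vs weak binders), not experimental
#' truth. When a miRNA has too few candidates to fill its quota, the deficit
#' is filled with the next most extreme unused pairs from other miRNAs
#' (most stable remaining for the positive half, most unstable remaining for
#' the negative half, ties by miRNA then target id), keeping the total at
#' 2 or 4 records per miRNA whenever the table is large enough.
#'
#' @param table Interaction data.frame with `mirna_id`, `target_id`,
#'   `energy` and, for trR, `label`.
#' @param mode `"trA"`, `"trB"`, `"trC"` or `"trR"`.
#' @param seed Integer seed (used by trR only).
#' @param size trR sample size; must not exceed `nrow(table)`.
#' @return An object of class `training_set`: list with `records` (columns
#'   `mirna_id, target_id, label, energy`), `mode`, `seed`.
#' @export
build_training_set <- function(table, mode = c("trA", "trB", "trC", "trR"),
                               seed = NULL, size = NULL) {
  mode <- match.arg(mode)
  if (nrow(table) == 0) stop("empty interaction table")
  if (mode == "trR") {
    if (is.null(seed)) stop("trR requires a seed")
    if (is.null(size)) stop("trR requires a size")
    if (size > nrow(table)) stop("trR size exceeds table size")
    idx <- withr::with_seed(seed, sample.int(nrow(table), size))
    rec <- table[sort(idx), , drop = FALSE]
    if (!"label" %in% names(rec)) rec$label <- "unlabelled"
    rownames(rec) <- NULL
    return(structure(list(records = rec[, c("mirna_id", "target_id", "label",
                                            "energy")],
                          mode = mode, seed = seed),
                     class = "training_set"))
  }

  ranked <- rank_pairs_by_energy(table)
  per_half <- if (mode == "trA") 1L else 2L
  pos_rows <- list(); neg_rows <- list(); used <- character(0)
  for (mir in names(ranked)) {
    d <- ranked[[mir]]
    m <- nrow(d)
    if (mode %in% c("trA", "trB")) {
      pk <- .pick_extremes(m, per_half)
    } else { # trC: extremes plus the candidates nearest the median energy
      pk <- .pick_extremes(m, 1L)
      free <- setdiff(seq_len(m), c(pk$pos, pk$neg))
      if (length(free) > 0) {
        med <- stats::median(d$energy)
        ord <- free[order(abs(d$energy[free] - med), d$energy[free],
                          d$target_id[free])]
        mid <- sort(utils::head(ord, 2))  # sorted: more stable first
        if (length(mid) >= 1) pk$pos <- c(pk$pos, mid[1])
        if (length(mid) >= 2) pk$neg <- c(pk$neg, mid[2])
      }
    }
    pos_rows[[mir]] <- d[pk$pos, , drop = FALSE]
    neg_rows[[mir]] <- d[pk$neg, , drop = FALSE]
  }
  pos <- do.call(rbind, pos_rows); neg <- do.call(rbind, neg_rows)
  used <- paste(c(pos$mirna_id, neg$mirna_id),
                c(pos$target_id, neg$target_id), sep = "|")

  # fill per-miRNA deficits from other miRNAs' next most extreme unused pairs
  M <- length(ranked)
  want <- per_half * M
  pool <- table[!(paste(table$mirna_id, table$target_id, sep = "|") %in% used),
                , drop = FALSE]
  pool <- pool[order(pool$energy, pool$mirna_id, pool$target_id), ,
               drop = FALSE]
  if (nrow(pos) < want) {
    take <- min(want - nrow(pos), nrow(pool))
    add <- pool[seq_len(take), , drop = FALSE]   # most stable remaining
    pos <- rbind(pos, add)
    pool <- pool[-seq_len(take), , drop = FALSE]
  }
  if (nrow(neg) < want) {
    take <- min(want - nrow(neg), nrow(pool))
    add <- pool[rev(seq_len(nrow(pool)))[seq_len(take)], , drop = FALSE]
    neg <- rbind(neg, add)                        # most unstable remaining
  }

  rec <- rbind(
    data.frame(mirna_id = pos$mirna_id, target_id = pos$target_id,
               label = "positive", energy = pos$energy,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = neg$mirna_id, target_id = neg$target_id,
               label = "negative", energy = neg$energy,
               stringsAsFactors = FALSE))
  rownames(rec) <- NULL
  structure(list(records = rec, mode = mode, seed = seed),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("training set ", x$mode, ": ", nrow(x$records), " records (",
      sum(x$records$label == "positive"), " positive / ",
      sum(x$records$label == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' Generate negative pairs by permutation
#'
#' Draws non-interacting (miRNA, gene) pairs uniformly without replacement
#' from the cross product of the positives' miRNAs with the gene universe,
#' excluding every known positive — the standard mock-negative construction
#' when experimentally verified non-interactions are unavailable.
#'
#' @param positives Data.frame with `mirna_id`, `target_id` (the known
#'   interactions to exclude).
#' @param gene_universe Character vector of candidate target genes.
#' @param seed Integer seed; output is reproducible per seed.
#' @param n Number of negatives requested; must not exceed the number of
#'   available non-positive combinations.
#' @return Data.frame with columns `mirna_id`, `target_id`,
#'   `label = "negative"`.
#' @export
generate_negatives_by_permutation <- function(positives, gene_universe, seed,
                                              n) {
  mirnas <- sort(unique(positives$mirna_id))
  genes <- sort(unique(gene_universe))
  pos_key <- paste(positives$mirna_id, positives$target_id, sep = "|")
  excl <- sum(positives$mirna_id %in% mirnas & positives$target_id %in% genes)
  total <- length(mirnas) * length(genes) - excl
  if (n > total)
    stop("insufficient non-positive combinations: requested ", n,
         " but only ", total, " exist")
  withr::with_seed(seed, {
    space <- length(mirnas) * length(genes)
    if (space <= 2e6) {
      all_idx <- seq_len(space) - 1L
      keys <- paste(mirnas[all_idx %/% length(genes) + 1L],
                    genes[all_idx %% length(genes) + 1L], sep = "|")
      avail <- all_idx[!(keys %in% pos_key)]
      pick <- sample(avail, n)
    } else {
      pick <- integer(0)
      while (length(pick) < n) {
        cand <- sample.int(space, min(space, 2 * (n - length(pick)))) - 1L
        keys <- paste(mirnas[cand %/% length(genes) + 1L],
                      genes[cand %% length(genes) + 1L], sep = "|")
        cand <- cand[!(keys %in% pos_key)]
        pick <- unique(c(pick, cand))
      }
      pick <- pick[seq_len(n)]
    }
    data.frame(mirna_id = mirnas[pick %/% length(genes) + 1L],
               target_id = genes[pick %% length(genes) + 1L],
               label = "negative", stringsAsFactors = FALSE)
  })
}

#' Enforce a positive/negative ratio by subsampling
#'
#' Subsamples the two sides without replacement to the largest sizes
#' attaining exactly the requested P/N ratio.
#'
#' @param pos,neg Data.frames of positive and negative records.
#' @param ratio P/N ratio as a positive number (1 = balanced, 0.5 = 1:2).
#' @param seed Integer seed.
#' @return List with elements `pos` and `neg`, subsampled.
#' @export
enforce_pn_ratio <- function(pos, neg, ratio = 1, seed = 1) {
  if (ratio <= 0) stop("ratio must be positive")
  np <- min(nrow(pos), floor(nrow(neg) * ratio))
  nn <- floor(np / ratio + 1e-9)
  if (np < 1 || nn < 1)
    stop("unattainable P/N ratio ", ratio, " with ", nrow(pos),
         " positives and ", nrow(neg), " negatives")
  withr::with_seed(seed, {
    list(pos = pos[sort(sample.int(nrow(pos), np)), , drop = FALSE],
         neg = neg[sort(sample.int(nrow(neg), nn)), , drop = FALSE])
  })
}

#' Stratified k-fold assignment
#'
#' Partitions records into `k` folds with per-fold class counts within one
#' record of the global proportions. Within each class the assignment is a
#' seeded random shuffle; fold sizes differ by at most one.
#'
#' @param labels Vector of class labels (one per record).
#' @param k Number of folds, `2 <= k <= length(labels)`.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k) aligned to `labels`.
#' @export
stratified_kfold <- function(labels, k, seed = 1) {
  n <- length(labels)
  if (k > n) stop("k exceeds the number of records")
  if (k < 2) stop("k must be at least 2")
  fold <- integer(n)
  counter <- 0L
  withr::with_seed(seed, {
    for (cl in sort(unique(as.character(labels)))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- counter + length(idx)
    }
  })
  fold
}

#' Subset records by a gene list
#'
#' Keeps the records whose target belongs to a gene list (e.g. genes with a
#' particular functional annotation), preserving order. An empty
#' intersection is allowed.
#'
#' @param set A `training_set` or a data.frame with a `target_id` column.
#' @param gene_ids Character vector of target ids to keep.
#' @return Object of the same type, subsetted.
#' @export
subset_by_gene_list <- function(set, gene_ids) {
  if (inherits(set, "training_set")) {
    set$records <- set$records[set$records$target_id %in% gene_ids, ,
                               drop = FALSE]
    rownames(set$records) <- NULL
    return(set)
  }
  out <- set[set$target_id %in% gene_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
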