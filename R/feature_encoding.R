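# Encoders that turn heterogeneous per-tool outputs for one (miRNA, target)
# pair into the fixed-order numeric feature vector defined by a registry.

.norm_rna <- function(seq) {
  s <- chartr("T", "U", toupper(seq))
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "U"))
  if (length(bad) > 0)
    stop("non-ACGU/T character in sequence: ", paste(bad, collapse = ", "))
  s
}

#' Encode observed seed types as a 7-dimensional indicator
#'
#' Builds the binary seed-type vector: one dimension per canonical seed
#' class, set to 1 when that class was observed for the pair by any
#' seed-aware tool.
#'
#' @param observed Character vector (or empty) of observed seed-type names.
#' @param canon Ordered canonical list, default [canonical_seed_types()].
#' @return Named integer vector of length `length(canon)` with values 0/1.
#' @examples
#' encode_seed_types(c("8mer"))
#' @export
encode_seed_types <- function(observed, canon = canonical_seed_types()) {
  observed <- unique(observed[nzchar(observed)])
  unknown <- setdiff(observed, canon)
  if (length(unknown) > 0)
    stop("unknown seed type(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(canon, collapse = ", "))
  structure(as.integer(canon %in% observed), names = canon)
}

#' Nucleotide composition of a binding site
#'
#' Converts a binding-site range on the target into the fractions of
#' A, C, G and U over the bound subsequence plus the AU content
#' (fraction A + fraction U). With no site the five values are all 0,
#' the convention for pairs a tool did not report on.
#'
#' @param target_seq Target RNA sequence (DNA alphabet accepted, T mapped to
#'   U). May be `NULL` when `site` is `NULL`.
#' @param site `NULL`, or a binding site: list/vector with `start` and `end`,
#'   1-based inclusive, `1 <= start <= end <= nchar(target_seq)`.
#' @return Named numeric vector `c(A=, C=, G=, U=, AU=)`; the four fractions
#'   sum to 1 for a present site and to 0 for an absent one.
#' @examples
#' encode_nucleotide_composition("AUGC", c(start = 1, end = 4))
#' @export
encode_nucleotide_composition <- function(target_seq, site = NULL) {
  if (is.null(site)) return(c(A = 0, C = 0, G = 0, U = 0, AU = 0))
  start <- as.numeric(site[["start"]]); end <- as.numeric(site[["end"]])
  if (is.na(start) || is.na(end) || start < 1 || start > end)
    stop("invalid binding site: need 1 <= start <= end")
  s <- .norm_rna(target_seq)
  if (end > nchar(s)) stop("binding site extends past target end")
  sub <- strsplit(substr(s, start, end), "")[[1]]
  n <- length(sub)
  f <- c(A = sum(sub == "A"), C = sum(sub == "C"),
         G = sum(sub == "G"), U = sum(sub == "U")) / n
  c(f, AU = unname(f["A"] + f["U"]))
}

#' One-hot encoding of a tool's categorical output
#'
#' miRanda results fall into 4 classes (good/non-good mirSVR score crossed
#' with conserved/non-conserved miRNA: `S_C`, `S_0`, `0_C`, `0_0`) and
#' STarMirDB results into 6 (3' UTR/CDS/5' UTR crossed with seed/seedless:
#' `3US`, `3ULS`, `CS`, `CLS`, `5US`, `5ULS`). A pair with no record from
#' the tool gets the all-zero vector.
#'
#' @param tool `"miRanda"` or `"STarMirDB"`.
#' @param category_label One label from the tool's class set, or `NULL` for
#'   a missing record.
#' @return Named integer one-hot vector over the tool's class set.
#' @export
encode_categorical_tool_output <- function(tool, category_label = NULL) {
  levels <- switch(tool,
                   "miRanda" = miranda_categories(),
                   "STarMirDB" = starmirdb_categories(),
                   stop("no categorical encoding for tool '", tool, "'"))
  if (is.null(category_label) || is.na(category_label))
    return(structure(integer(length(levels)), names = levels))
  if (!category_label %in% levels)
    stop("unknown ", tool, " category '", category_label, "'; accepted: ",
         paste(levels, collapse = ", "))
  structure(as.integer(levels == category_label), names = levels)
}

# Split one pair's long-format rows for one tool into records (a tool may
# legitimately report several sites; repeated field names delimit records).
.tool_field_list <- function(rows, tool, aggregate) {
  idx <- stats::ave(seq_len(nrow(rows)), rows$field, FUN = seq_along)
  n_rec <- max(idx)
  if (n_rec > 1 && aggregate == "error")
    stop("duplicate records for tool '", tool,
         "'; enable aggregate = \"most_stable\" to keep one")
  recs <- lapply(seq_len(n_rec), function(k) {
    r <- rows[idx == k, , drop = FALSE]
    structure(as.list(r$value), names = r$field)
  })
  if (n_rec == 1) return(recs[[1]])
  # keep the record with the most stable (most negative) energy field
  energy_fields <- c("mfe", "dg_total", "ddg", "folding_energy", "dg_duplex",
                     "dg_hybrid")
  en <- vapply(recs, function(rec) {
    f <- intersect(energy_fields, names(rec))
    if (length(f) == 0) return(Inf)
    suppressWarnings(as.numeric(rec[[f[1]]]))
  }, numeric(1))
  recs[[which.min(en)]]
}

.num_or_zero <- function(v) {
  if (is.null(v)) return(0)
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) 0 else x
}

#' Assemble the feature vector for one (miRNA, target) pair
#'
#' Maps the pair's tool records onto the registry: continuous fields are
#' copied, binding positions are normalized by target length, site ranges
#' are converted to nucleotide composition where the target sequence is
#' available, categorical outputs and seed types become indicator groups.
#' Every dimension sourced from a tool with no record for the pair is 0, so
#' sparse tool coverage degrades gracefully rather than invalidating the
#' pair.
#'
#' @param mirna_id,target_id Pair identifiers; all `records` rows must
#'   reference this pair.
#' @param records Long-format data.frame with columns
#'   `mirna_id, target_id, tool, field, value` (see [read_tool_table()]).
#' @param target_seq Target RNA sequence or `NULL`; without it,
#'   position-normalized and composition features are 0.
#' @param registry A `feature_registry`, default [default_registry()].
#' @param aggregate `"error"` (default) rejects multiple records from one
#'   tool for the pair; `"most_stable"` keeps the record with the most
#'   negative energy field.
#' @return Named numeric vector aligned to `registry$name`.
#' @export
assemble_feature_vector <- function(mirna_id, target_id, records,
                                    target_seq = NULL,
                                    registry = default_registry(),
                                    aggregate = c("error", "most_stable")) {
  aggregate <- match.arg(aggregate)
  out <- structure(numeric(nrow(registry)), names = registry$name)
  if (nrow(records) > 0) {
    if (!all(records$mirna_id == mirna_id & records$target_id == target_id))
      stop("records reference a different pair than (", mirna_id, ", ",
           target_id, ")")
    unknown <- setdiff(unique(records$tool), supported_tools())
    if (length(unknown) > 0)
      stop("unknown tool(s): ", paste(unknown, collapse = ", "))
  }
  tlen <- if (is.null(target_seq)) NA_real_ else nchar(target_seq)
  seed_canon <- registry$level[registry$kind == "seed"]

  for (tool in unique(registry$tool)) {
    rows <- records[records$tool == tool, , drop = FALSE]
    if (nrow(rows) == 0) next
    fl <- .tool_field_list(rows, tool, aggregate)
    ri <- which(registry$tool == tool)
    comp <- NULL
    for (i in ri) {
      kind <- registry$kind[i]; field <- registry$field[i]
      out[i] <- switch(kind,
        continuous = .num_or_zero(fl[[field]]),
        binary = as.numeric(.num_or_zero(fl[[field]]) != 0),
        position = {
          p <- .num_or_zero(fl[[field]])
          if (is.na(tlen) || tlen == 0 || p == 0) 0 else min(1, p / tlen)
        },
        onehot = {
          v <- encode_categorical_tool_output(tool, fl[["category"]])
          as.numeric(v[[registry$level[i]]])
        },
        seed = {
          obs <- if (is.null(fl[["seed_types"]])) character(0)
                 else strsplit(fl[["seed_types"]], "[;,]")[[1]]
          v <- encode_seed_types(trimws(obs), canon = seed_canon)
          as.numeric(v[[registry$level[i]]])
        },
        composition = {
          if (is.null(comp)) {
            st <- fl[["site_start"]]; en <- fl[["site_end"]]
            comp <- if (is.null(target_seq) || is.null(st) || is.null(en))
              c(A = 0, C = 0, G = 0, U = 0, AU = 0)
            else encode_nucleotide_composition(
              target_seq, c(start = as.numeric(st), end = as.numeric(en)))
          }
          comp[[registry$level[i]]]
        },
        stop("unknown registry kind '", kind, "'"))
    }
  }
  out
}

#' Assemble the feature matrix for a set of pairs
#'
#' Vectorized wrapper around [assemble_feature_vector()]: one row per pair
#' in `pairs`, columns in registry order. Pairs absent from the tool table
#' yield all-zero rows.
#'
#' @param tool_table Long-format tool output table
#'   (`mirna_id, target_id, tool, field, value`).
#' @param pairs Data.frame with columns `mirna_id`, `target_id`.
#' @param target_seqs Named character vector of target sequences
#'   (names = target ids), or `NULL`.
#' @param registry A `feature_registry`.
#' @param aggregate See [assemble_feature_vector()].
#' @return Numeric matrix `nrow(pairs) x nrow(registry)` with rownames
#'   `mirna_id|target_id`.
#' @export
assemble_feature_matrix <- function(tool_table, pairs, target_seqs = NULL,
                                    registry = default_registry(),
                                    aggregate = c("error", "most_stable")) {
  aggregate <- match.arg(aggregate)
  key <- function(m, t) paste(m, t, sep = "|")
  tt_key <- key(tool_table$mirna_id, tool_table$target_id)
  split_tt <- split(seq_len(nrow(tool_table)), tt_key)
  x <- matrix(0, nrow = nrow(pairs), ncol = nrow(registry),
              dimnames = list(key(pairs$mirna_id, pairs$target_id),
                              registry$name))
  for (i in seq_len(nrow(pairs))) {
    k <- key(pairs$mirna_id[i], pairs$target_id[i])
    idx <- split_tt[[k]]
    recs <- if (is.null(idx)) tool_table[0, , drop = FALSE]
            else tool_table[idx, , drop = FALSE]
    seq_i <- if (is.null(target_seqs)) NULL
             else target_seqs[[pairs$target_id[i]]]
    x[i, ] <- assemble_feature_vector(pairs$mirna_id[i], pairs$target_id[i],
                                      recs, seq_i, registry, aggregate)
  }
  x
}
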