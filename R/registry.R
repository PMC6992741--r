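#' Supported upstream prediction tools
#'
#' The fixed set of miRNA-target prediction tools whose outputs the feature
#' encoder understands. Tool names are matched exactly in the interchange
#' table.
#'
#' @return Character vector of the 11 tool names.
#' @export
supported_tools <- function() {
  c("RNA22", "RNAhybrid", "TargetScan", "PITA", "miRanda", "RNAduplex",
    "microT-CDS", "STarMirDB", "PACCMIT-CDS", "MBSTAR", "TarPmiR")
}

#' Canonical seed types
#'
#' Default ordered list of the seven canonical seed-match classes used for
#' the 7-dimensional seed-type indicator. The identity of the seven classes
#' is configurable; this default covers the classes commonly reported by
#' seed-aware tools, ordered from strongest canonical match to seedless.
#'
#' @return Character vector of length 7.
#' @export
canonical_seed_types <- function() {
  c("8mer", "7mer-m8", "7mer-A1", "6mer", "offset-6mer", "CDS-seed",
    "seedless")
}

#' @rdname encode_categorical_tool_output
#' @export
miranda_categories <- function() c("S_C", "S_0", "0_C", "0_0")

#' @rdname encode_categorical_tool_output
#' @export
starmirdb_categories <- function() c("3US", "3ULS", "CS", "CLS", "5US", "5ULS")

feature_categories <- function() {
  c("energy", "scoring function", "evolution evidence", "binding type",
    "sequence property", "structure")
}

.reg_rows <- function(tool, kind, field, names, category, level = NA_character_) {
  data.frame(name = names, category = category, tool = tool, kind = kind,
             field = field, level = level, stringsAsFactors = FALSE)
}

.reg_positional <- function(tool, prefix) {
  rbind(
    .reg_rows(tool, "position", "site_start", paste0(prefix, "_site_start"),
              "binding type"),
    .reg_rows(tool, "position", "site_end", paste0(prefix, "_site_end"),
              "binding type")
  )
}

.reg_composition <- function(tool, prefix) {
  .reg_rows(tool, "composition", "site_start",
            paste0(prefix, "_comp_", c("A", "C", "G", "U", "AU")),
            "sequence property", level = c("A", "C", "G", "U", "AU"))
}

#' The default feature registry
#'
#' Builds the shipped feature registry: the ordered, category-tagged list of
#' every numeric dimension extracted from the supported tools' outputs. Each
#' feature belongs to exactly one of six categories (energy, scoring
#' function, evolution evidence, binding type, sequence property,
#' structure). The registry order is the feature-vector order and is fixed
#' by construction.
#'
#' Per feature the registry records the source tool, the interchange-table
#' field it is read from, and an encoding kind:
#' \describe{
#'   \item{continuous}{the field value copied as a numeric (missing tool
#'     record contributes 0);}
#'   \item{binary}{a 0/1 flag;}
#'   \item{position}{a binding coordinate normalized by target length into
#'     `[0, 1]` (used for all position fields, including the position-only
#'     tools PITA and MBSTAR);}
#'   \item{onehot}{one member of a tool's categorical encoding (the 4
#'     miRanda score/conservation classes, the 6 STarMirDB region/seed
#'     classes);}
#'   \item{seed}{one member of the 7-dimensional seed-type indicator;}
#'   \item{composition}{one of the A/C/G/U fractions or the AU content of
#'     the bound target subsequence, computed from the binding site
#'     coordinates and the target sequence.}
#' }
#'
#' @param seed_types Ordered character vector of the seven canonical seed
#'   types (default [canonical_seed_types()]).
#' @return A data.frame of class `feature_registry` with columns
#'   `name`, `category`, `tool`, `kind`, `field`, `level`.
#' @examples
#' reg <- default_registry()
#' nrow(reg)
#' table(reg$category)
#' @export
default_registry <- function(seed_types = canonical_seed_types()) {
  if (length(seed_types) != 7 || anyDuplicated(seed_types))
    stop("seed_types must be 7 distinct names")
  parts <- list()

  # every tool contributes its binary binding call
  parts$calls <- .reg_rows(supported_tools(), "binary", "call",
                           paste0(gsub("[^A-Za-z0-9]", "", supported_tools()),
                                  "_call"),
                           "binding type")

  parts$rna22 <- rbind(
    .reg_rows("RNA22", "continuous", "p_value", "RNA22_p_value",
              "scoring function"),
    .reg_rows("RNA22", "continuous", "folding_energy", "RNA22_folding_energy",
              "energy"))

  parts$rnahybrid <- rbind(
    .reg_rows("RNAhybrid", "continuous", "mfe", "RNAhybrid_mfe", "energy"),
    .reg_rows("RNAhybrid", "continuous", "p_value", "RNAhybrid_p_value",
              "scoring function"),
    .reg_positional("RNAhybrid", "RNAhybrid"))

  parts$targetscan <- rbind(
    .reg_rows("TargetScan", "continuous", "context_score",
              "TargetScan_context_score", "scoring function"),
    .reg_rows("TargetScan", "continuous", "pct", "TargetScan_Pct",
              "evolution evidence"),
    .reg_rows("TargetScan", "seed", "seed_types",
              paste0("TargetScan_seed_", gsub("[^A-Za-z0-9]", "", seed_types)),
              "binding type", level = seed_types),
    .reg_positional("TargetScan", "TargetScan"),
    .reg_composition("TargetScan", "TargetScan"))

  parts$pita <- rbind(
    .reg_rows("PITA", "continuous", "ddg", "PITA_ddG", "structure"),
    .reg_rows("PITA", "continuous", "dg_duplex", "PITA_dG_duplex",
              "structure"),
    .reg_rows("PITA", "continuous", "dg_open", "PITA_dG_open", "structure"),
    .reg_rows("PITA", "position", "position", "PITA_position", "binding type"))

  parts$miranda <- rbind(
    .reg_rows("miRanda", "continuous", "alignment_score",
              "miRanda_alignment_score", "sequence property"),
    .reg_rows("miRanda", "continuous", "mirsvr_score", "miRanda_mirSVR_score",
              "scoring function"),
    .reg_rows("miRanda", "binary", "conservation", "miRanda_conservation",
              "evolution evidence"),
    .reg_rows("miRanda", "onehot", "category",
              paste0("miRanda_", miranda_categories()), "scoring function",
              level = miranda_categories()),
    .reg_positional("miRanda", "miRanda"),
    .reg_composition("miRanda", "miRanda"))

  parts$rnaduplex <- rbind(
    .reg_rows("RNAduplex", "continuous", "mfe", "RNAduplex_mfe", "energy"),
    .reg_positional("RNAduplex", "RNAduplex"),
    .reg_composition("RNAduplex", "RNAduplex"))

  parts$microt <- .reg_rows("microT-CDS", "continuous", "mitg_score",
                            "microTCDS_miTG_score", "scoring function")

  parts$starmirdb <- rbind(
    .reg_rows("STarMirDB", "continuous", "logistic_prob",
              "STMDB_logistic_prob", "scoring function"),
    .reg_rows("STarMirDB", "onehot", "category",
              paste0("STMDB_", starmirdb_categories()), "binding type",
              level = starmirdb_categories()),
    .reg_rows("STarMirDB", "continuous", "dg_hybrid", "STMDB_dG_hybrid",
              "structure"),
    .reg_rows("STarMirDB", "continuous", "dg_nucl", "STMDB_dG_nucl",
              "structure"),
    .reg_rows("STarMirDB", "continuous", "dg_total", "STMDB_dG_total",
              "structure"),
    .reg_rows("STarMirDB", "continuous", "accessibility",
              "STMDB_accessibility", "structure"),
    .reg_positional("STarMirDB", "STMDB"),
    .reg_composition("STarMirDB", "STMDB"))

  parts$paccmit <- .reg_rows("PACCMIT-CDS", "continuous", "p_value",
                             "PACCMITCDS_p_value", "scoring function")

  parts$mbstar <- rbind(
    .reg_rows("MBSTAR", "position", "position", "MBSTAR_position",
              "binding type"),
    .reg_rows("MBSTAR", "binary", "seed_match", "MBSTAR_seed_match",
              "binding type"))

  parts$tarpmir <- rbind(
    .reg_rows("TarPmiR", "continuous", "binding_prob",
              "TarPmiR_binding_prob", "scoring function"),
    .reg_rows("TarPmiR", "binary", "m_e_motif", "TarPmiR_m_e_motif",
              "scoring function"))

  reg <- do.call(rbind, unname(parts))
  rownames(reg) <- NULL
  stopifnot(!anyDuplicated(reg$name),
            all(reg$category %in% feature_categories()),
            all(reg$tool %in% supported_tools()))
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

#' Read / write a feature registry configuration
#'
#' The registry is a plain YAML list; each entry carries `name`, `category`,
#' `tool`, `kind`, `field` and, for group members, `level`. Reading
#' validates uniqueness of names, known categories and known tools.
#'
#' @param path File path.
#' @param registry A `feature_registry` (for writing).
#' @return `read_registry()` returns a `feature_registry`;
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  entries <- yaml::read_yaml(path)
  reg <- do.call(rbind, lapply(entries, function(e) {
    data.frame(name = e$name, category = e$category, tool = e$tool,
               kind = e$kind,
               field = e$field,
               level = if (is.null(e$level)) NA_character_ else e$level,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(reg$name)) stop("duplicate feature names in registry")
  if (!all(reg$category %in% feature_categories()))
    stop("unknown feature category in registry")
  if (!all(reg$tool %in% supported_tools()))
    stop("unknown tool in registry; supported: ",
         paste(supported_tools(), collapse = ", "))
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(seq_len(nrow(registry)), function(i) {
    e <- as.list(registry[i, c("name", "category", "tool", "kind", "field",
                               "level")])
    if (is.na(e$level)) e$level <- NULL
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
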