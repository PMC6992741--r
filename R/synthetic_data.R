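# Synthetic study generator: ground-truth interactions, a two-component
# binding-energy distribution, RNA sequences and per-tool output tables
# with controllable operating characteristics. Everything is reproducible
# from the config seed; each operation draws from a fixed sub-stream
# (seed + small offset) so the pieces can also be regenerated in isolation.

.sub_seed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L

#' Per-tool operating profiles for the generator
#'
#' Each profile sets the tool's sensitivity and specificity (probability of
#' calling a true interaction / true non-interaction correctly), the
#' coverage fraction of pairs it emits a record for at all, and the noise
#' s.d. of its continuous score payloads. The defaults emulate the spread
#' observed across published benchmark panels: a few strong sequence/ML
#' tools, several conservative high-specificity low-sensitivity tools, and
#' mid-range energy-based tools.
#'
#' @param sensitivity,specificity,coverage,score_noise Optional scalars
#'   overriding the per-tool defaults uniformly (handy for simulation
#'   studies that sweep operating characteristics).
#' @return Named list (one entry per supported tool) of profile lists.
#' @export
default_tool_profiles <- function(sensitivity = NULL, specificity = NULL,
                                  coverage = NULL, score_noise = NULL) {
  sn <- c("RNA22" = 0.76, "RNAhybrid" = 0.85, "TargetScan" = 0.97,
          "PITA" = 0.10, "miRanda" = 0.20, "RNAduplex" = 0.80,
          "microT-CDS" = 0.28, "STarMirDB" = 0.46, "PACCMIT-CDS" = 0.08,
          "MBSTAR" = 0.29, "TarPmiR" = 0.96)
  sp <- c("RNA22" = 0.88, "RNAhybrid" = 0.80, "TargetScan" = 0.91,
          "PITA" = 0.99, "miRanda" = 0.97, "RNAduplex" = 0.75,
          "microT-CDS" = 0.99, "STarMirDB" = 0.72, "PACCMIT-CDS" = 0.99,
          "MBSTAR" = 0.71, "TarPmiR" = 0.92)
  out <- lapply(supported_tools(), function(t) {
    list(sensitivity = if (is.null(sensitivity)) unname(sn[t]) else sensitivity,
         specificity = if (is.null(specificity)) unname(sp[t]) else specificity,
         coverage = if (is.null(coverage)) 0.9 else coverage,
         score_noise = if (is.null(score_noise)) 1 else score_noise)
  })
  names(out) <- supported_tools()
  out
}

#' Generator configuration
#'
#' Defines the synthetic study: how many miRNAs and targets, the
#' two-component Gaussian binding-energy model (true interactions are drawn
#' from a more stable component than non-interactions), the per-tool
#' operating profiles, and the sequence model.
#'
#' @param n_mirnas Number of miRNAs (default 50).
#' @param targets_per_mirna True targets per miRNA (default 20).
#' @param n_genes Size of the gene universe (default
#'   `10 * targets_per_mirna`); targets are drawn from it, so genes are
#'   shared between miRNAs as in real interactomes.
#' @param n_negatives Permutation negatives to generate (default: as many
#'   as there are positives).
#' @param energy List with `pos_mean`, `pos_sd`, `neg_mean`, `neg_sd` in
#'   kcal/mol. Defaults -25±3 (interacting) and -12±3 (non-interacting):
#'   overlapping unimodal components with the interacting one more stable.
#' @param tools Per-tool profiles, see [default_tool_profiles()].
#' @param sequence List with `target_length`, `mirna_length`, `site_length`,
#'   `gc` (GC fraction).
#' @param seed Integer master seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_mirnas = 50, targets_per_mirna = 20,
                             n_genes = 10 * targets_per_mirna,
                             n_negatives = NULL,
                             energy = list(pos_mean = -25, pos_sd = 3,
                                           neg_mean = -12, neg_sd = 3),
                             tools = default_tool_profiles(),
                             sequence = list(target_length = 1000,
                                             mirna_length = 22,
                                             site_length = 22, gc = 0.5),
                             seed = 1) {
  stopifnot(n_mirnas > 0, targets_per_mirna > 0,
            n_genes >= targets_per_mirna,
            energy$pos_sd > 0, energy$neg_sd > 0,
            energy$pos_mean < energy$neg_mean,
            sequence$gc >= 0, sequence$gc <= 1,
            sequence$target_length >= sequence$site_length)
  for (p in tools) {
    stopifnot(p$sensitivity >= 0, p$sensitivity <= 1,
              p$specificity >= 0, p$specificity <= 1,
              p$coverage >= 0, p$coverage <= 1, p$score_noise >= 0)
  }
  if (is.null(n_negatives)) n_negatives <- n_mirnas * targets_per_mirna
  structure(list(n_mirnas = n_mirnas, targets_per_mirna = targets_per_mirna,
                 n_genes = n_genes, n_negatives = n_negatives,
                 energy = energy, tools = tools, sequence = sequence,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate ground-truth interactions
#'
#' Draws each miRNA's true targets uniformly from the gene universe and
#' fabricates an equal-size (configurable) set of permutation negatives
#' disjoint from the positives.
#'
#' @param config A [generator_config()].
#' @return List with `positives`, `negatives` (data.frames `mirna_id`,
#'   `target_id`, `label`) and `universe` (character vector of gene ids).
#' @export
simulate_interactions <- function(config) {
  mirnas <- sprintf("mir_%04d", seq_len(config$n_mirnas))
  universe <- sprintf("gene_%05d", seq_len(config$n_genes))
  positives <- withr::with_seed(.sub_seed(config$seed, 1L), {
    do.call(rbind, lapply(mirnas, function(m) {
      data.frame(mirna_id = m,
                 target_id = sort(sample(universe,
                                         config$targets_per_mirna)),
                 label = "positive", stringsAsFactors = FALSE)
    }))
  })
  negatives <- generate_negatives_by_permutation(
    positives, universe, seed = .sub_seed(config$seed, 2L),
    n = config$n_negatives)
  list(positives = positives, negatives = negatives, universe = universe)
}

#' Simulate binding energies from the two-component model
#'
#' Each pair's binding free energy is a Gaussian draw from its label's
#' component; true interactions are stochastically more stable (more
#' negative energies).
#'
#' @param pairs Data.frame with a `label` column
#'   (`"positive"`/`"negative"`).
#' @param config A [generator_config()].
#' @return Numeric vector of energies (kcal/mol) aligned to `pairs`.
#' @export
simulate_energies <- function(pairs, config) {
  e <- config$energy
  withr::with_seed(.sub_seed(config$seed, 3L), {
    pos <- pairs$label == "positive"
    out <- numeric(nrow(pairs))
    out[pos] <- stats::rnorm(sum(pos), e$pos_mean, e$pos_sd)
    out[!pos] <- stats::rnorm(sum(!pos), e$neg_mean, e$neg_sd)
    out
  })
}

.random_rna <- function(n, len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = ""),
    character(1))
}

#' Simulate miRNA and target sequences (and binding sites)
#'
#' Random RNA of the configured length and GC content for every gene in
#' the universe and every miRNA; optionally one in-bounds binding site per
#' requested pair.
#'
#' @param config A [generator_config()].
#' @param universe Gene ids to generate targets for.
#' @param mirnas miRNA ids.
#' @param pairs Optional data.frame of pairs to assign binding sites to.
#' @return List with `targets` and `mirnas` (named character vectors) and,
#'   when `pairs` is given, `sites` (data.frame `mirna_id, target_id,
#'   start, end`).
#' @export
simulate_sequences <- function(config, universe, mirnas, pairs = NULL) {
  sq <- config$sequence
  withr::with_seed(.sub_seed(config$seed, 4L), {
    targets <- stats::setNames(
      .random_rna(length(universe), sq$target_length, sq$gc), universe)
    mir <- stats::setNames(
      .random_rna(length(mirnas), sq$mirna_length, sq$gc), mirnas)
    out <- list(targets = targets, mirnas = mir)
    if (!is.null(pairs)) {
      start <- sample.int(sq$target_length - sq$site_length + 1L,
                          nrow(pairs), replace = TRUE)
      out$sites <- data.frame(mirna_id = pairs$mirna_id,
                              target_id = pairs$target_id,
                              start = start,
                              end = start + sq$site_length - 1L,
                              stringsAsFactors = FALSE)
    }
    out
  })
}

# Payload fields for one tool's emitted records. Continuous payloads are
# drawn from two overlapping distributions conditioned on the emitted call,
# so they carry graded signal beyond the binary call itself.
.tool_payload <- function(tool, call, profile, site_start, site_end,
                          target_len) {
  n <- length(call)
  noise <- profile$score_noise
  sig <- function(mu1, mu0) stats::rnorm(n, ifelse(call == 1, mu1, mu0), noise)
  pval <- function() ifelse(call == 1, stats::rbeta(n, 0.5, 6),
                            stats::rbeta(n, 2, 2))
  mfe <- function() stats::rnorm(n, ifelse(call == 1, -25, -14), 3 * noise)
  f <- list(call = call)
  if (tool == "RNA22") {
    f$p_value <- pval(); f$folding_energy <- mfe()
  } else if (tool == "RNAhybrid") {
    f$mfe <- mfe(); f$p_value <- pval()
    f$site_start <- site_start; f$site_end <- site_end
  } else if (tool == "TargetScan") {
    f$context_score <- sig(-0.4, -0.05)
    f$pct <- pmin(1, pmax(0, sig(0.7, 0.3)))
    seed_pool <- canonical_seed_types()
    f$seed_types <- ifelse(call == 1,
                           seed_pool[sample.int(5, n, replace = TRUE)],
                           ifelse(stats::runif(n) < 0.7, "seedless",
                                  seed_pool[sample.int(7, n, replace = TRUE)]))
    f$site_start <- site_start; f$site_end <- site_end
  } else if (tool == "PITA") {
    f$ddg <- sig(-10, -2); f$dg_duplex <- mfe(); f$dg_open <- sig(12, 8)
    f$position <- site_start
  } else if (tool == "miRanda") {
    f$alignment_score <- sig(160, 120); f$mirsvr_score <- sig(-1.2, -0.2)
    f$conservation <- as.integer(stats::runif(n) <
                                   ifelse(call == 1, 0.7, 0.3))
    good <- stats::runif(n) < ifelse(call == 1, 0.8, 0.25)
    f$category <- paste0(ifelse(good, "S", "0"), "_",
                         ifelse(f$conservation == 1, "C", "0"))
    f$site_start <- site_start; f$site_end <- site_end
  } else if (tool == "RNAduplex") {
    f$mfe <- mfe(); f$site_start <- site_start; f$site_end <- site_end
  } else if (tool == "microT-CDS") {
    f$mitg_score <- pmin(1, pmax(0, sig(0.85, 0.4)))
  } else if (tool == "STarMirDB") {
    f$logistic_prob <- pmin(1, pmax(0, sig(0.8, 0.35)))
    region <- sample(c("3U", "C", "5U"), n, replace = TRUE,
                     prob = c(0.7, 0.2, 0.1))
    seeded <- stats::runif(n) < ifelse(call == 1, 0.8, 0.3)
    f$category <- paste0(region, ifelse(seeded, "S", "LS"))
    f$dg_hybrid <- mfe(); f$dg_nucl <- sig(6, 9); f$dg_total <- mfe()
    f$accessibility <- pmin(1, pmax(0, sig(0.6, 0.4)))
    f$site_start <- site_start; f$site_end <- site_end
  } else if (tool == "PACCMIT-CDS") {
    f$p_value <- pval()
  } else if (tool == "MBSTAR") {
    f$position <- site_start
    f$seed_match <- as.integer(stats::runif(n) <
                                 ifelse(call == 1, 0.8, 0.2))
  } else if (tool == "TarPmiR") {
    f$binding_prob <- pmin(1, pmax(0, sig(0.8, 0.3)))
    f$m_e_motif <- as.integer(stats::runif(n) <
                                ifelse(call == 1, 0.75, 0.25))
  }
  f
}

#' Simulate the per-tool output tables
#'
#' For every tool and every truth pair, the tool emits a record with
#' probability `coverage`; an emitted record's binding call is Bernoulli
#' with the tool's sensitivity on true interactions and specificity on
#' non-interactions, and the score/position/seed-type payloads are filled
#' consistently with the call.
#'
#' @param truth Data.frame `mirna_id, target_id, label`.
#' @param config A [generator_config()].
#' @param sites Optional per-pair binding sites (from
#'   [simulate_sequences()]); defaults to fresh uniform sites.
#' @return Long-format tool table (`mirna_id, target_id, tool, field,
#'   value`) ready for [assemble_feature_matrix()].
#' @export
simulate_tool_outputs <- function(truth, config, sites = NULL) {
  sq <- config$sequence
  withr::with_seed(.sub_seed(config$seed, 5L), {
    pieces <- list()
    for (tool in names(config$tools)) {
      prof <- config$tools[[tool]]
      covered <- which(stats::runif(nrow(truth)) < prof$coverage)
      if (length(covered) == 0) next
      lab <- truth$label[covered]
      p_call <- ifelse(lab == "positive", prof$sensitivity,
                       1 - prof$specificity)
      call <- as.integer(stats::runif(length(covered)) < p_call)
      if (is.null(sites)) {
        s <- sample.int(sq$target_length - sq$site_length + 1L,
                        length(covered), replace = TRUE)
        e <- s + sq$site_length - 1L
      } else {
        key <- paste(truth$mirna_id[covered], truth$target_id[covered],
                     sep = "|")
        skey <- paste(sites$mirna_id, sites$target_id, sep = "|")
        idx <- match(key, skey)
        s <- sites$start[idx]; e <- sites$end[idx]
        miss <- is.na(s)
        if (any(miss)) {
          s[miss] <- sample.int(sq$target_length - sq$site_length + 1L,
                                sum(miss), replace = TRUE)
          e[miss] <- s[miss] + sq$site_length - 1L
        }
      }
      payload <- .tool_payload(tool, call, prof, s, e, sq$target_length)
      for (field in names(payload)) {
        pieces[[paste(tool, field)]] <- data.frame(
          mirna_id = truth$mirna_id[covered],
          target_id = truth$target_id[covered],
          tool = tool, field = field,
          value = as.character(payload[[field]]),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out[order(out$mirna_id, out$target_id, out$tool, out$field), ,
        drop = FALSE]
  })
}

#' Simulate a complete synthetic study
#'
#' One-stop wrapper: interactions, energies, sequences, binding sites and
#' tool outputs, all from one config.
#'
#' @param config A [generator_config()].
#' @return List with `interactions` (labelled, energy-annotated pair
#'   table), `tool_table`, `sequences` and `truth` (= `interactions`
#'   without the energy column).
#' @export
simulate_study <- function(config = generator_config()) {
  sim <- simulate_interactions(config)
  interactions <- rbind(sim$positives, sim$negatives)
  interactions$energy <- simulate_energies(interactions, config)
  seqs <- simulate_sequences(config, sim$universe,
                             unique(interactions$mirna_id),
                             pairs = interactions)
  tool_table <- simulate_tool_outputs(interactions, config,
                                      sites = seqs$sites)
  list(interactions = interactions, tool_table = tool_table,
       sequences = seqs,
       truth = interactions[, c("mirna_id", "target_id", "label")])
}
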