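# Protein-pair scoring: the log-normalized domain-interaction score D_mn, the
# classifier's predicted-pair ratio P_ij, their linear fusion
# P_mn = A*D_mn + B*P_ij, the 7x7 (A, B) lattice search, and the
# fn/fp-balanced threshold selection.

#' Build a domain-pair interaction-score table
#'
#' Lookup is orientation-insensitive. `s_max` is the largest stored score.
#' The background score — assigned to pairs missing from the table — defaults
#' to the 20th percentile of the stored scores (ascending sort, element
#' `ceiling(0.2 * n)`, 1-based); pass `background_score` to override (the
#' published analysis used 1.74 for its own table).
#'
#' @param scores data frame with columns `id_a`, `id_b`, `lambda` (> 0)
#' @param background_score optional override, > 1
#' @param interaction_cutoff score above which a pair counts as interacting
#' @return object of class `score_table`
#' @export
score_table <- function(scores, background_score = NULL,
                        interaction_cutoff = 1.5) {
  stopifnot(all(c("id_a", "id_b", "lambda") %in% names(scores)))
  lambda <- as.numeric(scores$lambda)
  if (any(lambda <= 0)) stop("lambda scores must be positive")
  key <- .pair_key(scores$id_a, scores$id_b)
  if (anyDuplicated(key)) stop("duplicate domain pair in score table")
  s_max <- max(lambda)
  if (s_max <= 1) stop("s_max must exceed 1 (log s_max must be positive)")
  if (is.null(background_score)) {
    sorted <- sort(lambda)
    background_score <- sorted[ceiling(0.2 * length(sorted))]
  }
  if (background_score <= 1)
    stop("background score must exceed 1, got ", background_score)
  structure(list(lambda = stats::setNames(lambda, key), s_max = s_max,
                 background_score = background_score,
                 interaction_cutoff = interaction_cutoff),
            class = "score_table")
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up lambda scores for domain pairs (background fallback when absent)
#' @param table a [score_table()]
#' @param id_a,id_b domain id vectors
#' @return numeric lambda values
#' @export
lookup_score <- function(table, id_a, id_b) {
  stopifnot(inherits(table, "score_table"))
  lam <- table$lambda[.pair_key(id_a, id_b)]
  lam[is.na(lam)] <- table$background_score
  unname(lam)
}

#' A protein record: id plus ordered domain architecture
#' @param protein_id identifier
#' @param domain_ids character vector, length >= 1 (repeats allowed)
#' @return object of class `protein_record`
#' @export
protein_record <- function(protein_id, domain_ids) {
  if (!length(domain_ids)) stop("empty architecture for '", protein_id, "'")
  structure(list(protein_id = protein_id,
                 domain_ids = as.character(domain_ids)),
            class = "protein_record")
}

#' Enumerate the domain-pair cross product of two proteins
#'
#' `num_ddi = |domains(a)| * |domains(b)|`; duplicate domains in an
#' architecture yield duplicate pairs, by design.
#'
#' @param prot_a,prot_b `protein_record` objects
#' @return list with `pairs` (data frame `id_a`, `id_b`) and `num_ddi`
#' @export
enumerate_domain_pairs <- function(prot_a, prot_b) {
  stopifnot(inherits(prot_a, "protein_record"),
            inherits(prot_b, "protein_record"))
  grid <- expand.grid(id_a = prot_a$domain_ids, id_b = prot_b$domain_ids,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  list(pairs = grid, num_ddi = nrow(grid))
}

#' Normalize an interaction score onto [0, 1]
#'
#' `d = log(lambda) / log(s_max)`, clamped below at 0 (lambda < 1 would give
#' a negative value) and equal to 1 at `lambda = s_max`.
#'
#' @param lambda positive score(s)
#' @param s_max table maximum, > 1
#' @return normalized score(s) in [0, 1]
#' @export
normalize_score <- function(lambda, s_max) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (s_max <= 1) stop("s_max must exceed 1")
  pmin(pmax(log(lambda) / log(s_max), 0), 1)
}

#' Domain-interaction score of a protein pair
#'
#' Looks up lambda for every enumerated domain pair (background fallback for
#' missing ones) and aggregates the normalized scores. Aggregation is `max`
#' by default — the strongest single piece of domain-level evidence, which
#' reduces to the plain normalized score for single-domain proteins — with
#' `mean` available.
#'
#' @inheritParams enumerate_domain_pairs
#' @param table a [score_table()]
#' @param aggregate `"max"` (default) or `"mean"`
#' @return `d_mn` in [0, 1]
#' @export
protein_pair_dscore <- function(prot_a, prot_b, table,
                                aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  ep <- enumerate_domain_pairs(prot_a, prot_b)
  lam <- lookup_score(table, ep$pairs$id_a, ep$pairs$id_b)
  d <- normalize_score(lam, table$s_max)
  if (aggregate == "max") max(d) else mean(d)
}

#' Predicted-pair ratio of a protein pair
#'
#' `p_ij = Num_predicted / Num_DDI`: the fraction of the enumerated domain
#' pairs the DDI classifier labels interacting.
#'
#' @inheritParams enumerate_domain_pairs
#' @param model a trained `ddi_model`
#' @param feature_matrix per-domain raw feature matrix
#'   ([domain_feature_matrix()])
#' @param params the training `minmax_normalizer`
#' @return `p_ij` in [0, 1]
#' @export
predicted_ratio <- function(prot_a, prot_b, model, feature_matrix, params) {
  ep <- enumerate_domain_pairs(prot_a, prot_b)
  pv <- build_pair_vectors(feature_matrix, ep$pairs, params)
  sum(predict_pairs(model, pv$vectors)) / ep$num_ddi
}

#' Fuse the two channels into the PPI probability
#'
#' `p_mn = a_weight * d_mn + b_weight * p_ij`; with `a_weight + b_weight = 1`
#' and both inputs in [0, 1] the result is in [0, 1]. Defaults are the final
#' published weights A = B = 0.5.
#'
#' @param d_mn,p_ij channel values in [0, 1] (vectorized)
#' @param a_weight,b_weight nonnegative weights
#' @return fused score(s)
#' @export
fuse_scores <- function(d_mn, p_ij, a_weight = 0.5, b_weight = 0.5) {
  stopifnot(a_weight >= 0, b_weight >= 0)
  a_weight * d_mn + b_weight * p_ij
}

#' Fusion configuration
#'
#' @param a_weight,b_weight fusion weights (final model: 0.5 / 0.5)
#' @param lattice_values grid for both A and B: 0 to 0.6 step 0.1 (7 values,
#'   49 lattice points)
#' @param threshold_grid coarse thresholds: 0.10 to 0.55 step 0.05 (10)
#' @param chosen_threshold decision threshold for [predict_ppi()]
#' @param aggregate d_mn aggregation rule, `"max"` or `"mean"`
#' @return object of class `fusion_config`
#' @export
fusion_config <- function(a_weight = 0.5, b_weight = 0.5,
                          lattice_values = seq(0, 0.6, by = 0.1),
                          threshold_grid = seq(0.10, 0.55, by = 0.05),
                          chosen_threshold = 0.26,
                          aggregate = "max") {
  structure(list(a_weight = a_weight, b_weight = b_weight,
                 lattice_values = lattice_values,
                 threshold_grid = threshold_grid,
                 chosen_threshold = chosen_threshold,
                 aggregate = aggregate),
            class = "fusion_config")
}

# d_mn and p_ij for every protein pair in a pair table
.channel_scores <- function(ppi_pairs, proteins, model, feature_matrix,
                            params, table, aggregate = "max") {
  miss <- setdiff(unique(c(ppi_pairs$id_a, ppi_pairs$id_b)), names(proteins))
  if (length(miss))
    stop("no architecture for protein(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  n <- nrow(ppi_pairs)
  d_mn <- numeric(n); p_ij <- numeric(n)
  for (i in seq_len(n)) {
    pa <- proteins[[ppi_pairs$id_a[i]]]
    pb <- proteins[[ppi_pairs$id_b[i]]]
    d_mn[i] <- protein_pair_dscore(pa, pb, table, aggregate)
    p_ij[i] <- predicted_ratio(pa, pb, model, feature_matrix, params)
  }
  data.frame(id_a = ppi_pairs$id_a, id_b = ppi_pairs$id_b,
             d_mn = d_mn, p_ij = p_ij)
}

.threshold_counts <- function(scores, labels, thr) {
  confusion_counts(truth = labels, predicted = as.integer(scores >= thr))
}

# best threshold among cands by the (|fn - fp|, fn + fp) lexicographic rule;
# candidates are visited in order and replace the incumbent only on strict
# improvement, so earlier candidates win full ties (pass the grid ascending
# for the smaller-threshold tie-break; pass the coarse pick first during
# refinement so ties keep it, as in the published 0.25/0.26/0.27 check)
.pick_threshold <- function(scores, labels, cands) {
  best <- NULL
  for (thr in cands) {
    r <- fn_fp_rates(.threshold_counts(scores, labels, thr))
    key <- c(abs(r["fn_rate"] - r["fp_rate"]), r["fn_rate"] + r["fp_rate"])
    if (is.null(best) || .lex_less(key, best$key)) best <- list(thr = thr, key = key)
  }
  best$thr
}

# exact lexicographic comparison: both keys are ratios of the same integer
# counts, so analytically equal keys are bitwise equal and a tolerance would
# only blur genuine differences
.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Select the decision threshold balancing fn and fp
#'
#' Over the coarse grid, picks the threshold minimizing `|fn - fp|` (rates as
#' in [fn_fp_rates()]), with `fn + fp` then the smaller threshold as
#' tie-breaks; then re-evaluates at the pick's +/- 0.01 neighbors under the
#' same rule (the published procedure's 0.25/0.26/0.27 refinement).
#' Labels are assigned by `score >= threshold`.
#'
#' @param scores fused p_mn scores
#' @param labels 0/1 truth, both classes present
#' @param threshold_grid coarse candidate thresholds
#' @return list with `threshold`, `table` (per-coarse-threshold diagnostics:
#'   threshold, TP, TN, FP, FN, fn_rate, fp_rate, Acc, SN, SPE, Pre, MCC,
#'   F1), `refined` (the +/- 0.01 comparison table), and `auc`
#' @export
select_threshold <- function(scores, labels,
                             threshold_grid = seq(0.10, 0.55, by = 0.05)) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  tab <- do.call(rbind, lapply(threshold_grid, function(thr) {
    cc <- .threshold_counts(scores, labels, thr)
    m <- suppressWarnings(compute_metrics(cc))
    data.frame(threshold = thr, tp = cc$tp, tn = cc$tn, fp = cc$fp,
               fn = cc$fn, fn_rate = m$fn_rate, fp_rate = m$fp_rate,
               acc = m$acc, sn = m$sn, spe = m$spe, pre = m$pre,
               mcc = m$mcc, f1 = m$f1)
  }))
  coarse <- .pick_threshold(scores, labels, sort(threshold_grid))
  refine_cands <- c(coarse - 0.01, coarse, coarse + 0.01)
  chosen <- .pick_threshold(scores, labels,
                            c(coarse, coarse - 0.01, coarse + 0.01))
  refined <- do.call(rbind, lapply(refine_cands, function(thr) {
    r <- fn_fp_rates(.threshold_counts(scores, labels, thr))
    data.frame(threshold = thr, fn_rate = r[["fn_rate"]],
               fp_rate = r[["fp_rate"]])
  }))
  list(threshold = chosen, table = tab, refined = refined,
       auc = roc_auc(scores, labels)$auc)
}

#' Lattice search over the fusion weights (A, B)
#'
#' Evaluates every point of the 7x7 lattice (A and B independently over
#' `lattice_values`): each point's fused scores are assessed at every coarse
#' threshold and the point's accuracy is the best over thresholds; its AUC is
#' threshold-free. Returns the point maximizing accuracy, with AUC then
#' smaller A as tie-breaks.
#'
#' @param d_mn,p_ij per-protein-pair channel scores
#' @param labels 0/1 truth
#' @param config a [fusion_config()]
#' @return list with `a_weight`, `b_weight`, `best_threshold`, and
#'   `diagnostics` (49-row data frame: a_weight, b_weight, best_threshold,
#'   accuracy, auc)
#' @export
lattice_search <- function(d_mn, p_ij, labels, config = fusion_config()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  grid <- expand.grid(a_weight = config$lattice_values,
                      b_weight = config$lattice_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    a <- grid$a_weight[k]; b <- grid$b_weight[k]
    p <- fuse_scores(d_mn, p_ij, a, b)
    accs <- vapply(config$threshold_grid, function(thr)
      mean((p >= thr) == labels), numeric(1))
    auc <- if (stats::sd(p) == 0) 0.5 else roc_auc(p, labels)$auc
    data.frame(a_weight = a, b_weight = b,
               best_threshold = config$threshold_grid[which.max(accs)],
               accuracy = 100 * max(accs), auc = auc)
  })
  diag <- do.call(rbind, rows)
  ord <- order(-diag$accuracy, -diag$auc, diag$a_weight, diag$b_weight)
  best <- diag[ord[1L], ]
  list(a_weight = best$a_weight, b_weight = best$b_weight,
       best_threshold = best$best_threshold, diagnostics = diag)
}

#' Score and label protein pairs end to end
#'
#' Computes both channels for every pair, fuses them with the configured
#' weights, and labels `1` iff `p_mn >= chosen_threshold`. Full provenance
#' (`d_mn`, `p_ij`, `p_mn`) is retained per pair.
#'
#' @param ppi_pairs data frame with `id_a`, `id_b` (optional `label`)
#' @param proteins named list of [protein_record()]s
#' @param model trained `ddi_model`
#' @param feature_matrix per-domain raw feature matrix
#' @param params training normalizer
#' @param table a [score_table()]
#' @param config a [fusion_config()]
#' @return data frame: id_a, id_b, d_mn, p_ij, p_mn, predicted_label
#'   (+ label if supplied)
#' @export
predict_ppi <- function(ppi_pairs, proteins, model, feature_matrix, params,
                        table, config = fusion_config()) {
  ch <- .channel_scores(ppi_pairs, proteins, model, feature_matrix, params,
                        table, config$aggregate)
  ch$p_mn <- fuse_scores(ch$d_mn, ch$p_ij, config$a_weight, config$b_weight)
  ch$predicted_label <- as.integer(ch$p_mn >= config$chosen_threshold)
  if ("label" %in% names(ppi_pairs)) ch$label <- as.integer(ppi_pairs$label)
  ch
}
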